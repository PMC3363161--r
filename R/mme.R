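#' Solve the genomic mixed model for all genotyped individuals
#'
#' Computes the BLUP solutions of `y = 1*mu + sum_k u_k + e`,
#' `u_k ~ N(0, K_k sigma2_k)`, for every genotyped individual, including
#' unphenotyped validation animals: `mu` by generalized least squares and
#' `u_k = sigma2_k K_k[, obs] V^{-1} (y_obs - mu)` with
#' `V = sum_k sigma2_k K_k[obs, obs] + sigma2_e I`.  These are exactly the
#' solutions of Henderson's mixed-model equations with the ridged inverse
#' relationship matrices.
#'
#' @param y Phenotypes for all individuals; `NA` marks unphenotyped
#'   (validation) individuals, which must still be present in the kernels.
#' @param varcomp A `reml_fit`, or a named numeric vector of variances whose
#'   names match `relationships` plus `"residual"`.
#' @param relationships Named list of relationship matrices over all
#'   individuals, in the same order/naming as the variance components.
#'
#' @return An `mme_solution`: `mu_hat`, tibble `solutions` with one column of
#'   random-effect solutions per kernel (`a_hat` for `additive`, `d_hat` for
#'   `dominance`, `aa_hat` for `epistatic`), and the variance components used.
#' @export
solve_mme <- function(y, varcomp, relationships) {
  if (inherits(varcomp, "reml_fit")) {
    vc <- stats::setNames(varcomp$components$variance, varcomp$components$term)
  } else vc <- varcomp
  terms <- setdiff(names(vc), "residual")
  if (!all(terms %in% names(relationships))) {
    abort("Variance components and relationship matrices do not match by name.")
  }
  obs <- !is.na(y)
  if (!any(obs)) abort("No phenotyped records.")
  n <- sum(obs)
  yo <- y[obs]
  V <- diag(vc[["residual"]], n)
  for (k in terms) V <- V + vc[[k]] * unclass(relationships[[k]])[obs, obs]
  ch <- tryCatch(chol(V), error = function(e)
    abort("Coefficient matrix is singular.", class = "gpqtl_singular"))
  Vi <- chol2inv(ch)
  w <- Vi %*% rep(1, n)
  mu_hat <- sum(w * yo) / sum(w)
  r <- Vi %*% (yo - mu_hat)

  sol <- tibble::tibble(id = seq_along(y))
  col_of <- c(additive = "a_hat", dominance = "d_hat", epistatic = "aa_hat")
  for (k in terms) {
    u <- vc[[k]] * drop(unclass(relationships[[k]])[, obs] %*% r)
    nm <- if (k %in% names(col_of)) col_of[[k]] else paste0(k, "_hat")
    sol[[nm]] <- u
  }
  structure(list(mu_hat = mu_hat, solutions = sol, varcomp = vc),
            class = "mme_solution")
}

#' @export
print.mme_solution <- function(x, ...) {
  cat(sprintf("Mixed-model solutions: mu_hat = %.4f, %d individuals\n",
              x$mu_hat, nrow(x$solutions)))
  invisible(x)
}

#' Backsolve allele substitution effects from GBLUP breeding values
#'
#' Recovers per-SNP allele substitution effects from genomic breeding values
#' through the relationship matrix:
#' `alpha = Zc' G^{-1} a_hat / (2 * sum(p * (1 - p)))`, with `Zc` the centered
#' genotype matrix `G` was built from.  This scaling satisfies the
#' reconstruction identity `Zc %*% alpha = a_hat` for breeding values in the
#' row space of `Zc`; the singular 1-direction that observed-frequency
#' centering introduces is handled by an augmented solve, and deeper rank
#' deficiency (fewer SNPs than individuals) by an eigen pseudo-inverse.
#' The per-SNP substitution-effect variance
#' `sigma2_alpha = sigma2_a / (2 * sum(p * (1 - p)))` is reported alongside.
#'
#' @param a_hat GEBV vector for the individuals `G` is indexed by.
#' @param X Dosage matrix `G` was built from.
#' @param G The additive `genomic_rel` built from `X` by [build_grm()];
#'   provenance is checked through the stored scaling denominator.
#' @param sigma2_a Additive genetic variance (for `sigma2_alpha`).
#' @return A `backsolved_effects`: tibble with `snp` and `alpha`, plus
#'   attribute `sigma2_alpha`.
#' @export
backsolve_effects <- function(a_hat, X, G, sigma2_a = NA_real_) {
  p <- allele_freqs(X)
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (!isTRUE(all.equal(denom, attr(G, "denominator"), tolerance = 1e-8))) {
    abort("G was not built from this genotype matrix (denominator mismatch).",
          class = "gpqtl_provenance")
  }
  Zc <- sweep(X, 2, 2 * p)
  Zc[, !poly] <- 0
  # centering by observed frequencies makes G singular in the 1-direction
  # (G 1 = 0) while GBLUP breeding values lie in range(G); solving the
  # 1-augmented system keeps the reconstruction Zc alpha = a_hat exact.
  # If G is rank-deficient beyond that (fewer SNPs than individuals), fall
  # back to the eigen pseudo-inverse, which is still exact on range(G).
  G0 <- unclass(G)
  n <- nrow(G0)
  tau <- mean(diag(G0))
  g_inv_a <- tryCatch(
    solve(G0 + tau * tcrossprod(rep(1, n)) / n, a_hat),
    error = function(e) NULL)
  if (is.null(g_inv_a)) {
    eg <- eigen(G0, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    g_inv_a <- drop(eg$vectors[, pos, drop = FALSE] %*%
                      (crossprod(eg$vectors[, pos, drop = FALSE], a_hat) /
                         eg$values[pos]))
  }
  alpha <- drop(crossprod(Zc, g_inv_a)) / denom
  structure(tibble::tibble(snp = seq_len(ncol(X)), alpha = alpha),
            sigma2_alpha = sigma2_a / denom,
            denominator = denom,
            class = c("backsolved_effects", "tbl_df", "tbl", "data.frame"))
}
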