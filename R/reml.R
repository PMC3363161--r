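#' REML variance components for genomic mixed models
#'
#' Estimates variance components of `y = 1*mu + sum_k u_k + e`,
#' `u_k ~ N(0, K_k sigma2_k)`, by restricted maximum likelihood: 5
#' expectation-maximization warm-start iterations followed by
#' average-information updates, falling back to EM for any iteration whose AI
#' proposal would leave the parameter space.  Convergence is declared when
#' the restricted log-likelihood changes by less than `tol`.  Components
#' driven to zero are pinned at a small boundary (`1e-8 * var(y)`) and
#' flagged.
#'
#' `gblup_reml()` is the model-level wrapper: model `"G1"` fits the additive
#' kernel only, `"G2"` adds a dominance kernel and `"G3"` an
#' additive-by-additive epistatic kernel.
#'
#' @param y Phenotypes of the individuals the kernels are indexed by; `NA`
#'   entries (validation individuals) are dropped for estimation.
#' @param kernels Named list of relationship matrices (all individuals).
#' @param tol Convergence tolerance on the restricted log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum iterations (default 200).
#'
#' @return A `reml_fit` with `components` (tibble: term, variance, pinned),
#'   `h2` (additive / total), `loglik`, `converged`, `n_iter`, `model`.
#' @export
reml_varcomp <- function(y, kernels, tol = 1e-8, max_iter = 200) {
  obs <- !is.na(y)
  yo <- y[obs]
  n <- length(yo)
  q <- length(kernels)
  if (n < q + 2) abort("Too few phenotyped records for the number of components.")
  Ks <- lapply(kernels, function(K) unclass(K)[obs, obs, drop = FALSE])
  vy <- var1(yo)
  bound <- 1e-8 * vy
  sig <- rep(vy / (q + 1), q + 1)              # components then residual
  ones <- rep(1, n)

  loglik <- -Inf
  trajectory <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    V <- diag(sig[q + 1], n)
    for (k in seq_len(q)) V <- V + sig[k] * Ks[[k]]
    ch <- tryCatch(chol(V), error = function(e)
      abort("V is not positive definite; check the relationship matrices.",
            class = "gpqtl_not_pd"))
    logdetV <- 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    w <- Vi %*% ones
    s <- sum(w)
    Py <- Vi %*% yo - w * (sum(w * yo) / s)
    ll <- -0.5 * (logdetV + log(s) + sum(yo * Py))
    trajectory <- c(trajectory, ll)

    # scores and average information for all components (incl. residual)
    tK <- vector("list", q + 1)
    trPK <- numeric(q + 1)
    ypKpy <- numeric(q + 1)
    for (k in seq_len(q + 1)) {
      K <- if (k <= q) Ks[[k]] else NULL
      if (k <= q) {
        trPK[k] <- sum(Vi * K) - sum(w * (K %*% w)) / s
        tK[[k]] <- K %*% Py
      } else {
        trPK[k] <- sum(diag(Vi)) - sum(w * w) / s
        tK[[k]] <- Py
      }
      ypKpy[k] <- sum(Py * tK[[k]])
    }

    if (abs(ll - loglik) < tol && it > 1) { converged <- TRUE; break }
    loglik <- ll

    new_sig <- sig
    use_em <- it <= 5
    if (!use_em) {
      AI <- matrix(0, q + 1, q + 1)
      for (k in seq_len(q + 1)) for (l in k:(q + 1)) {
        AI[k, l] <- AI[l, k] <-
          0.5 * (sum(tK[[k]] * (Vi %*% tK[[l]])) -
                 sum(w * tK[[k]]) * sum(w * tK[[l]]) / s)
      }
      score <- 0.5 * (ypKpy - trPK)
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(step)) {
        use_em <- TRUE
      } else {
        off <- sig + step < 0
        new_sig <- sig + step
        # components an AI step would drive negative are pinned at the
        # boundary; the rest take an EM update for this iteration
        if (any(off)) {
          new_sig[off] <- bound
          new_sig[!off] <- (sig[!off]^2 * ypKpy[!off] + n * sig[!off] -
                              sig[!off]^2 * trPK[!off]) / n
        }
      }
    }
    if (use_em) {
      for (k in seq_len(q + 1)) {
        new_sig[k] <- (sig[k]^2 * ypKpy[k] + n * sig[k] - sig[k]^2 * trPK[k]) / n
      }
    }
    sig <- pmax(new_sig, bound)
  }
  if (!converged) {
    abort(paste0("REML did not converge in ", max_iter, " iterations.\n",
                 "Log-likelihood trajectory tail: ",
                 paste(signif(tail(trajectory, 5), 8), collapse = ", ")),
          class = "gpqtl_no_convergence")
  }
  terms <- c(names(kernels), "residual")
  comp <- tibble::tibble(term = terms, variance = sig,
                         pinned = sig <= bound * (1 + 1e-12))
  add <- if ("additive" %in% terms) sig[match("additive", terms)] else sig[1]
  structure(list(components = comp, h2 = add / sum(sig), loglik = loglik,
                 converged = converged, n_iter = it, n = n,
                 model = NULL),
            class = "reml_fit")
}

#' @rdname reml_varcomp
#' @param relationships Named list with elements `additive` and optionally
#'   `dominance`, `epistatic` (from [build_grm()] and friends).
#' @param model `"G1"` (additive), `"G2"` (additive + dominance) or `"G3"`
#'   (additive + epistatic).
#' @export
gblup_reml <- function(y, relationships, model = c("G1", "G2", "G3"),
                       tol = 1e-8, max_iter = 200) {
  model <- match.arg(model)
  need <- switch(model, G1 = "additive",
                 G2 = c("additive", "dominance"),
                 G3 = c("additive", "epistatic"))
  if (!all(need %in% names(relationships))) {
    abort(sprintf("Model %s needs relationship matrices: %s.",
                  model, paste(need, collapse = ", ")))
  }
  fit <- reml_varcomp(y, relationships[need], tol = tol, max_iter = max_iter)
  fit$model <- model
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit%s: n = %d, loglik = %.4f (%d iterations)\n",
              if (!is.null(x$model)) paste0(" [", x$model, "]") else "",
              x$n, x$loglik, x$n_iter))
  print(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("  h2 = %.4f\n", x$h2))
  invisible(x)
}

#' @describeIn reml_varcomp Variance components as a tibble.
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @export
tidy.reml_fit <- function(x, ...) x$components

#' @describeIn reml_varcomp One-row summary (variances, h2, loglik).
#' @export
glance.reml_fit <- function(x, ...) {
  wide <- stats::setNames(as.list(x$components$variance),
                          paste0("var_", x$components$term))
  tibble::as_tibble(c(list(model = x$model %||% NA_character_), wide,
                      list(h2 = x$h2, loglik = x$loglik, n = x$n,
                           n_iter = x$n_iter)))
}
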