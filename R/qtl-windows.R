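#' Sliding-window GEBV variance proportions
#'
#' For each window of `window_size` consecutive SNPs within a chromosome
#' (sliding by one SNP, never crossing chromosome boundaries), computes the
#' variance across individuals of the window's GEBV contribution
#' `g_iw = sum_{j in w} Xc_ij * a_j`, standardized by the total GEBV
#' variance.  Per-SNP variance shares `var(Xc_j a_j) / var(GEBV)` are
#' attached for the window's reported peak SNP search.
#'
#' With `use_samples = TRUE` and a fit carrying retained effect samples, the
#' proportion is the posterior mean of the per-sample ratio instead of the
#' ratio at the posterior-mean effects.
#'
#' @param X Dosage matrix of the individuals the variance is taken over.
#' @param effects A `wgr_fit`, a `backsolved_effects`, or a numeric vector of
#'   per-SNP (substitution) effects aligned to the columns of `X`.
#' @param map Marker map tibble (`snp`, `chromosome`, `position`).
#' @param window_size Number of consecutive SNPs per window (default 10).
#' @param use_samples Average the per-sample ratios over retained posterior
#'   samples (slower) instead of using posterior-mean effects.
#'
#' @return A `window_variance_table` tibble: `window_id`, `chromosome`,
#'   `first_snp`, `last_snp` (1-based, inclusive), `proportion`, and
#'   `peak_snp`/`peak_share`, with the per-SNP shares in attribute
#'   `snp_share`.
#' @export
window_variances <- function(X, effects, map, window_size = 10,
                             use_samples = FALSE) {
  fit <- NULL
  if (inherits(effects, "wgr_fit")) {
    fit <- effects
    p <- fit$pars$allele_freqs
    eff <- fit$effects$effect_a
    if (!is.null(fit$effects[["effect_d"]])) {
      eff <- eff + fit$effects$effect_d * (1 - 2 * p)
    }
  } else if (inherits(effects, "backsolved_effects")) {
    eff <- effects$alpha
    p <- allele_freqs(X)
  } else {
    eff <- as.numeric(effects)
    p <- allele_freqs(X)
  }
  stopifnot(length(eff) == ncol(X), nrow(map) == ncol(X))
  if (any(table(map$chromosome) < window_size)) {
    abort("window_size exceeds the SNP count of a chromosome.",
          class = "gpqtl_invalid_design")
  }
  Xc <- sweep(X, 2, 2 * p)

  # window bounds per chromosome (sliding by one SNP)
  bounds <- dplyr::bind_rows(lapply(split(map$snp, map$chromosome), function(s) {
    first <- s[seq_len(length(s) - window_size + 1)]
    tibble::tibble(first_snp = first, last_snp = first + window_size - 1)
  }))
  bounds$chromosome <- map$chromosome[bounds$first_snp]
  bounds$window_id <- seq_len(nrow(bounds))

  contrib <- sweep(Xc, 2, eff, `*`)
  gebv <- rowSums(contrib)
  vtot <- var1(gebv)
  snp_share_vec <- apply(contrib, 2, var1)

  if (vtot <= 0) {
    warn("All effects are zero; window variance proportions set to 0.")
    prop <- rep(0, nrow(bounds))
    snp_share_vec <- rep(0, ncol(X))
  } else {
    snp_share_vec <- snp_share_vec / vtot
    if (use_samples && !is.null(fit) && !is.null(fit$samples$effect_a)) {
      store <- fit$samples$effect_a
      if (!is.null(fit$samples[["effect_d"]])) {
        store <- store + fit$samples$effect_d * (1 - 2 * p)
      }
      prop <- window_var_samples_cpp(Xc, store, bounds$first_snp - 1L,
                                     bounds$last_snp - 1L)
    } else {
      cs <- cbind(0, t(apply(contrib, 1, cumsum)))   # individuals x (k + 1)
      prop <- vapply(seq_len(nrow(bounds)), function(w) {
        g <- cs[, bounds$last_snp[w] + 1] - cs[, bounds$first_snp[w]]
        var1(g) / vtot
      }, numeric(1))
    }
  }

  peak <- vapply(seq_len(nrow(bounds)), function(w) {
    idx <- bounds$first_snp[w]:bounds$last_snp[w]
    idx[which.max(snp_share_vec[idx])]
  }, integer(1))

  out <- tibble::tibble(window_id = bounds$window_id,
                        chromosome = bounds$chromosome,
                        first_snp = bounds$first_snp,
                        last_snp = bounds$last_snp,
                        proportion = as.numeric(prop),
                        peak_snp = peak,
                        peak_share = snp_share_vec[peak])
  attr(out, "snp_share") <- snp_share_vec
  attr(out, "window_size") <- window_size
  class(out) <- c("window_variance_table", class(out))
  out
}
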