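#' Call QTL from window variances (Bayesian methods)
#'
#' Significant windows are those whose variance proportions lie in the top
#' `(1 - pi_hat) * 100%` of all windows (BayesCpi mode) or exceed
#' `bayesb_multiplier` times the median background proportion (BayesB mode; a
#' declared formalization of a visual criterion).  Overlapping or adjacent
#' significant windows on the same chromosome are merged, and each merged
#' span yields one call at the SNP with the largest per-SNP variance share
#' (ties broken toward the lowest index).
#'
#' @param windows A `window_variance_table` from [window_variances()].
#' @param map Marker map tibble.
#' @param mode `"bayesCpi"` (quantile threshold from `pi_hat`) or `"bayesB"`
#'   (median-multiplier threshold).
#' @param pi_hat Posterior mean of pi (required for `"bayesCpi"` mode).
#' @param bayesb_multiplier Multiplier on the median background window
#'   proportion for `"bayesB"` mode (default 10).
#' @param method Label recorded in the output (defaults to `mode`).
#'
#' @return A `qtl_calls` tibble: `method`, `chromosome`, `snp`, `position`,
#'   `variance_share`, `first_snp`, `last_snp` (merged significant span),
#'   `n_windows`.
#' @export
call_qtl_bayes <- function(windows, map, mode = c("bayesCpi", "bayesB"),
                           pi_hat = NULL, bayesb_multiplier = 10,
                           method = NULL) {
  mode <- match.arg(mode)
  if (nrow(windows) == 0) abort("Empty window table.")
  if (mode == "bayesCpi") {
    if (is.null(pi_hat) || pi_hat <= 0 || pi_hat >= 1) {
      abort("bayesCpi mode needs pi_hat in (0, 1).")
    }
    thr <- stats::quantile(windows$proportion, probs = pi_hat, names = FALSE)
  } else {
    thr <- bayesb_multiplier * stats::median(windows$proportion)
  }
  sig <- windows[windows$proportion >= thr & windows$proportion > 0, ]
  merge_spans_to_calls(sig, map, attr(windows, "snp_share"),
                       method %||% mode)
}

#' Call QTL from backsolved GBLUP marker effects
#'
#' Flags SNPs whose absolute substitution effect exceeds
#' `mean(|alpha|) + k_sd * sd(|alpha|)` (a declared formalization of a visual
#' criterion), merges runs of flagged SNPs lying within `merge_within` SNPs
#' of each other on the same chromosome, and reports one call per run at the
#' largest `|alpha|`.
#'
#' @param alpha A `backsolved_effects` (or numeric vector of substitution
#'   effects aligned to the map).
#' @param map Marker map tibble.
#' @param k_sd Threshold in SD units above the mean absolute effect
#'   (default 4).
#' @param merge_within Maximum SNP-index gap between flagged SNPs merged into
#'   one call (default 10).
#' @return A `qtl_calls` tibble (see [call_qtl_bayes()]); the number of raw
#'   flagged SNPs is kept in attribute `n_flagged`.
#' @export
call_qtl_gblup <- function(alpha, map, k_sd = 4, merge_within = 10) {
  a <- if (inherits(alpha, "backsolved_effects")) alpha$alpha else as.numeric(alpha)
  if (length(a) == 0) abort("Empty effect vector.")
  stopifnot(length(a) == nrow(map))
  aa <- abs(a)
  thr <- mean(aa) + k_sd * stats::sd(aa)
  flagged <- which(aa > thr)
  calls <- empty_calls()
  if (length(flagged) > 0) {
    chrom <- map$chromosome[flagged]
    new_run <- c(TRUE, diff(flagged) > merge_within | diff(chrom) != 0)
    run_id <- cumsum(new_run)
    calls <- dplyr::bind_rows(lapply(split(flagged, run_id), function(idx) {
      peak <- idx[which.max(aa[idx])]
      tibble::tibble(method = "gblup", chromosome = map$chromosome[peak],
                     snp = peak, position = map$position[peak],
                     variance_share = NA_real_,
                     first_snp = min(idx), last_snp = max(idx),
                     n_windows = length(idx))
    }))
  }
  attr(calls, "n_flagged") <- length(flagged)
  class(calls) <- c("qtl_calls", class(calls))
  calls
}

merge_spans_to_calls <- function(sig, map, snp_share, method) {
  if (nrow(sig) == 0) {
    out <- empty_calls()
    class(out) <- c("qtl_calls", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(lapply(split(sig, sig$chromosome), function(s) {
    s <- s[order(s$first_snp), ]
    span_id <- cumsum(c(TRUE, s$first_snp[-1] > cummax(s$last_snp)[-nrow(s)] + 1))
    dplyr::bind_rows(lapply(split(s, span_id), function(sp) {
      idx <- min(sp$first_snp):max(sp$last_snp)
      peak <- idx[which.max(snp_share[idx])]
      tibble::tibble(method = method, chromosome = sp$chromosome[1],
                     snp = peak, position = map$position[peak],
                     variance_share = snp_share[peak],
                     first_snp = min(sp$first_snp), last_snp = max(sp$last_snp),
                     n_windows = nrow(sp))
    }))
  }))
  out <- out[order(out$chromosome, out$snp), ]
  class(out) <- c("qtl_calls", class(out))
  out
}

empty_calls <- function() {
  tibble::tibble(method = character(), chromosome = integer(), snp = integer(),
                 position = numeric(), variance_share = numeric(),
                 first_snp = integer(), last_snp = integer(),
                 n_windows = integer())
}

#' Score QTL calls against the simulated truth
#'
#' A call is a true positive if it lies within `tolerance_morgans` of a true
#' QTL on the same chromosome; each true QTL is credited at most once per
#' method (calls are assigned greedily by increasing distance), surplus calls
#' near an already-credited QTL count as false positives.
#'
#' @param calls A `qtl_calls` tibble (possibly several methods row-bound).
#' @param truth QTL architecture tibble (needs `qtl_id`, `chromosome`,
#'   `position`, `action`).
#' @param tolerance_morgans Matching tolerance in Morgans (default 0.05).
#' @return A list with `summary` (per method: `tp`, `fp`, `n_true`) and
#'   `detections` (per QTL x method: `detected`, `called_snp`, `distance`).
#' @export
evaluate_calls <- function(calls, truth, tolerance_morgans = 0.05) {
  methods <- unique(calls$method)
  det <- list()
  summ <- list()
  for (m in methods) {
    cm <- calls[calls$method == m, ]
    pairs <- tidyr::expand_grid(ci = seq_len(nrow(cm)), qi = seq_len(nrow(truth)))
    if (nrow(pairs) > 0) {
      pairs$dist <- abs(cm$position[pairs$ci] - truth$position[pairs$qi])
      pairs <- pairs[cm$chromosome[pairs$ci] == truth$chromosome[pairs$qi] &
                       pairs$dist <= tolerance_morgans, ]
      pairs <- pairs[order(pairs$dist), ]
    }
    qtl_hit <- rep(NA_integer_, nrow(truth))
    call_used <- rep(FALSE, nrow(cm))
    dist_hit <- rep(NA_real_, nrow(truth))
    for (r in seq_len(nrow(pairs))) {
      ci <- pairs$ci[r]; qi <- pairs$qi[r]
      if (!call_used[ci] && is.na(qtl_hit[qi])) {
        qtl_hit[qi] <- cm$snp[ci]
        dist_hit[qi] <- pairs$dist[r]
        call_used[ci] <- TRUE
      }
    }
    det[[m]] <- tibble::tibble(method = m, qtl_id = truth$qtl_id,
                               action = truth$action,
                               chromosome = truth$chromosome,
                               detected = !is.na(qtl_hit),
                               called_snp = qtl_hit, distance = dist_hit)
    summ[[m]] <- tibble::tibble(method = m, tp = sum(!is.na(qtl_hit)),
                                fp = nrow(cm) - sum(call_used),
                                n_calls = nrow(cm), n_true = nrow(truth))
  }
  list(summary = dplyr::bind_rows(summ), detections = dplyr::bind_rows(det))
}
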