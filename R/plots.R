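#' Plot per-SNP posterior summaries of a Bayesian fit
#'
#' Manhattan-style panels of the absolute posterior-mean effects and the
#' model frequencies along the genome.
#'
#' @param object A `wgr_fit`.
#' @param map Optional marker map; without it the x-axis is the SNP index.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wgr_fit <- function(object, map = NULL, ...) {
  df <- object$effects
  df$chromosome <- if (!is.null(map)) factor(map$chromosome[df$snp]) else factor(1)
  long <- tidyr::pivot_longer(
    dplyr::transmute(df, snp = .data$snp, chromosome = .data$chromosome,
                     `|effect|` = abs(.data$effect_a),
                     `model frequency` = .data$model_freq_a),
    cols = c("|effect|", "model frequency"),
    names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snp, y = .data$value,
                                     colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "SNP index", y = NULL,
                  title = sprintf("Single-SNP signals (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot window variance proportions along the genome
#'
#' @param windows A `window_variance_table`.
#' @param calls Optional `qtl_calls` to mark as vertical lines.
#' @param truth Optional QTL truth tibble to mark (dashed lines).
#' @return A ggplot object.
#' @export
plot_window_variances <- function(windows, calls = NULL, truth = NULL) {
  gg <- ggplot2::ggplot(windows,
                        ggplot2::aes(x = .data$first_snp, y = .data$proportion,
                                     colour = factor(.data$chromosome))) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = "window start (SNP index)",
                  y = "window variance / total GEBV variance",
                  title = "10-SNP window variances") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    gg <- gg + ggplot2::geom_vline(data = calls,
                                   ggplot2::aes(xintercept = .data$snp),
                                   linetype = 1, alpha = 0.4)
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    gg <- gg + ggplot2::geom_vline(data = truth,
                                   ggplot2::aes(xintercept = .data$snp),
                                   linetype = 2, alpha = 0.4)
  }
  gg
}

#' Plot backsolved marker effects along the genome
#'
#' @param alpha A `backsolved_effects`.
#' @param map Marker map tibble.
#' @return A ggplot object.
#' @export
plot_marker_effects <- function(alpha, map) {
  df <- tibble::tibble(snp = alpha$snp, alpha = abs(alpha$alpha),
                       chromosome = factor(map$chromosome[alpha$snp]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = .data$alpha,
                                   colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = "SNP index", y = "|allele substitution effect|",
                  title = "Backsolved marker effects (GBLUP)") +
    ggplot2::theme_minimal()
}
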