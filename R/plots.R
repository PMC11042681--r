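#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$density,
                               fill = .data$segment)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(
      xintercept = c(sum(object$segment == "utr5") / 3,
                     2 * sum(object$segment == "utr5")),
      linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "metagene position (5'UTR | CDS | 3'UTR)",
                  y = "peak density") +
    ggplot2::theme_minimal()
}

#' Volcano plot of bin-level differential methylation
#'
#' @param bin_results tibble from [nb_wald_test()].
#' @param p_cut significance line (default 0.05).
#' @return A ggplot object.
#' @export
plot_dm_volcano <- function(bin_results, p_cut = 0.05) {
  d <- bin_results[!is.na(bin_results$pvalue), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$pvalue),
                                  colour = .data$pvalue < p_cut)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (CASE vs CTRL)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' PCA scatter of samples after nuisance removal
#'
#' @param pca result of [pca_samples()].
#' @param colour design column mapped to point colour.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, colour = "condition") {
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
}

#' Insulin-expression mixture plot for beta-cell calls
#'
#' @param calls tibble from [gmm_beta_call()].
#' @return A ggplot object.
#' @export
plot_beta_calls <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$insulin,
                               fill = factor(.data$component))) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "insulin log-expression", y = "cells",
                  fill = "mode") +
    ggplot2::theme_minimal()
}
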