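#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' MA-style plot of a differential-expression fit
#'
#' Average adjusted log expression against log2 fold change, coloured by
#' class. Under a global shift with spike anchoring, the cloud sits
#' visibly below zero — the signature per-library normalization erases.
#'
#' @param object A [de_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$logCPM, y = .data$logFC,
                               colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")
    ) +
    ggplot2::labs(title = object$contrast,
                  x = "average log2 expression (size-adjusted)",
                  y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Normalization factors and effective sizes per sample
#'
#' @param factors Output of [tmm_factors()].
#' @return A ggplot of effective sizes (spike library size x TMM factor).
#' @export
plot_norm_factors <- function(factors) {
  ggplot2::ggplot(factors,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$effective_size)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "effective size (anchor reads x factor)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Global-shift estimates per sample
#'
#' Bar plot of the per-sample median normalized expression ratio against
#' the reference condition (see [global_shift()]); the spike-anchored
#' readout of total transcription per cell.
#'
#' @param shift Output of [global_shift()].
#' @return A ggplot.
#' @export
plot_global_shift <- function(shift) {
  ggplot2::ggplot(shift,
                  ggplot2::aes(x = .data$sample_id, y = .data$median_ratio,
                               fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "median expression ratio vs reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar plot of a ChIP group comparison
#'
#' Group means of spike-normalized region counts with significance stars
#' from [compare_groups()].
#'
#' @param comparison Output of [compare_groups()].
#' @return A ggplot.
#' @export
plot_chip_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, c("mean_a", "mean_b"),
                              names_to = "group", values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region_id, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = comparison,
      ggplot2::aes(x = .data$region_id,
                   y = pmax(.data$mean_a, .data$mean_b) * 1.05,
                   label = .data$stars),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "spike-normalized reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
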