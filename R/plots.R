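#' Plot per-signature enrichment scores across samples
#'
#' @param object An `enrichment_result` from [enrichment_matrix()].
#' @param ... Unused.
#' @return A ggplot: samples x signatures tile map of enrichment scores.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$signature,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a SPEC prediction
#'
#' Per-subset correlations as bars, with the fitted permutation null shown
#' as mean +/- 2 sd reference lines; the predicted subset is highlighted.
#'
#' @param object A `spec_result` from [run_spec()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spec_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$subset,
                                                      -.data$correlation),
                                   y = .data$correlation,
                                   fill = .data$predicted)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$null$fitted_mean,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$null$fitted_mean +
                          2 * object$null$fitted_sd,
                        linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#D55E00")) +
    ggplot2::labs(x = NULL, y = "correlation with query enrichment",
                  subtitle = sprintf("predicted: %s (p = %.3g)",
                                     object$predicted_subset,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a size-sweep result
#'
#' P-value (log scale) against query size, annotated with the predicted
#' subset at each size.
#'
#' @param sweep Tibble from [run_size_sweep()].
#' @param alpha Significance reference line (default 0.05).
#' @return A ggplot.
#' @export
plot_size_sweep <- function(sweep, alpha = 0.05) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$query_size,
                                      y = .data$p_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$predicted_subset),
                        size = 2) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "query size (genes)", y = "p-value",
                  colour = "predicted") +
    ggplot2::theme_minimal()
}

#' Plot a split-validation report
#'
#' Stacked outcome counts per subset in the four-cell layout
#' (correct/incorrect crossed with significant/non-significant).
#'
#' @param report A `validation_report` from [run_split_validation()].
#' @return A ggplot.
#' @export
plot_validation_report <- function(report) {
  df <- tidyr::pivot_longer(tibble::as_tibble(report),
                            cols = c("correct_significant", "correct_ns",
                                     "incorrect_significant", "incorrect_ns"),
                            names_to = "outcome", values_to = "count")
  df$outcome <- factor(df$outcome,
                       levels = c("correct_significant", "correct_ns",
                                  "incorrect_ns", "incorrect_significant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset, y = .data$count,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "replicates", fill = NULL) +
    ggplot2::theme_minimal()
}
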