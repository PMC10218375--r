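#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SHMT dose-response fit
#'
#' Observed (averaged) rates as points with the fitted single-hit
#' multitarget curve; the dashed vertical line marks the shoulder dose
#' Dq.
#'
#' @param object An [fit_shmt()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shmt_fit <- function(object, ...) {
  grid <- tibble::tibble(
    dose = seq(0, max(object$data$dose), length.out = 200))
  grid$rate <- shmt_rate(grid$dose, object$d0, object$m)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                            y = .data$rate)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$dq, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "Dose (Gy)", y = "Effect rate",
      title = sprintf("SHMT fit: D0 = %.1f Gy, m = %.2f, Dq = %.0f Gy",
                      object$d0, object$m, object$dq)) +
    ggplot2::theme_minimal()
}

#' Stacked mutation-spectrum proportions
#'
#' Stacked bar chart of category proportions per group from a spectrum
#' summary (see [aggregate_spectrum()] / [spectrum_from_counts()]).
#'
#' @param summary Spectrum summary tibble with `category`, `proportion`
#'   and a grouping column.
#' @param group Name of the grouping column (default `"group_label"`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(summary, group = "group_label") {
  summary <- tibble::as_tibble(summary)
  summary$category <- factor(summary$category, levels = category_levels)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[group]], y = .data$proportion,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Proportion of mutations (%)",
                  fill = "Category") +
    ggplot2::theme_minimal()
}
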