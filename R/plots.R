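#' Plot a QSPR fit
#'
#' Scatter of property against index with the fitted line, annotated with the
#' model statistics.
#'
#' @param object A [fit_qspr()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qspr_fit
#' @export
autoplot.qspr_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$A, slope = object$B, colour = "steelblue") +
    ggplot2::labs(
      x = object$index, y = object$property,
      title = sprintf("%s = %.4g %s %.4g * %s", object$property, object$A,
                      ifelse(object$B < 0, "-", "+"), abs(object$B), object$index),
      subtitle = sprintf("|r| = %.3f, r2 = %.3f, F(1,%d) = %.3g, p = %.3g",
                         object$r_abs, object$r2, object$n - 2, object$f_stat,
                         object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.qspr_fit <- function(x, ...) print(autoplot.qspr_fit(x, ...))

#' Plot the correlation profile of a QSPR report
#'
#' Bar chart of the absolute index-property correlations, one panel per
#' property.
#'
#' @param object A [run_qspr()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qspr_report
#' @export
autoplot.qspr_report <- function(object, ...) {
  if (is.null(object$correlations)) {
    rlang::abort("Report has no correlation table (indices-only run).",
                 class = "tiqspr_error_schema")
  }
  long <- tidyr::pivot_longer(object$correlations, -"index",
                              names_to = "property", values_to = "r_abs")
  long$index <- factor(long$index, levels = index_ids())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$r_abs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~property) +
    ggplot2::labs(x = NULL, y = "|r|") +
    ggplot2::theme_minimal()
}
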