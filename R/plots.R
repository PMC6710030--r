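#' Plot a fitted cloud, a study, or a sensitivity analysis
#'
#' `autoplot.ransac_fit()` shows a 2D projection of the cloud coloured by
#' inlier status against the fitted surface; `autoplot.congruence_study()`
#' the ITPR distributions by exposure group (or region) faceted by shape —
#' the study's boxplot figures; `autoplot.sensitivity_result()` the
#' CoV-RMSE tolerance curve with the chosen tolerance marked.
#'
#' @param object The fitted object.
#' @param data For `ransac_fit`, the cloud the fit was computed on.
#' @param axes Two coordinate names to project onto (default x, z).
#' @param what `"group"` or `"region"` stratification for studies.
#' @param ... Unused.
#' @return A ggplot.
#' @name spinefit-autoplot
NULL

#' @rdname spinefit-autoplot
#' @export
autoplot.ransac_fit <- function(object, data, axes = c("x", "z"), ...) {
  aug <- augment(object, data)
  ggplot2::ggplot(aug, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                    colour = .data$.inlier)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "#27ae60")) +
    ggplot2::labs(title = sprintf("%s fit: ITPR %.3f at eps %g mm",
                                  object$shape, object$itpr, object$epsilon),
                  x = paste(axes[1], "(mm)"), y = paste(axes[2], "(mm)"),
                  colour = "inlier") +
    ggplot2::theme_minimal()
}

#' @rdname spinefit-autoplot
#' @export
autoplot.congruence_study <- function(object, what = c("group", "region"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object$records,
                  ggplot2::aes(.data[[what]], .data$itpr, fill = .data[[what]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~shape) +
    ggplot2::labs(x = if (what == "group") "exposure group" else "spinal region",
                  y = "inliers-to-points ratio") +
    ggplot2::theme_minimal()
}

#' @rdname spinefit-autoplot
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$epsilon, .data$cov_rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "black")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "maximum inlier error (mm)",
                  y = "mean CoV-RMSE across clouds and shapes") +
    ggplot2::theme_minimal()
}
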