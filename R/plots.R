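#' Plot a pair of quality indicators at unit level
#'
#' Scatter plot of one standardized ratio against another, one point per
#' ICU, sized by the unit's admission count, with reference lines at 1
#' (performance as expected) on both axes.
#'
#' @param table An `indicator_table`.
#' @param pair One of `"SMR-SRR"`, `"SMR-SLOSR"`, `"SLOSR-SRR"`.
#' @param subgroup Subgroup to plot (default `"all"`).
#' @return A ggplot object.
#' @export
plot_indicator_pair <- function(table, pair = "SMR-SLOSR",
                                subgroup = "all") {
  pts <- scatter_export(table, pair, subgroup)
  parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    size = .data$n)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = parts[1], y = parts[2], size = "admissions",
                  title = sprintf("%s vs %s (%s)", parts[1], parts[2],
                                  subgroup)) +
    ggplot2::theme_minimal()
}

#' Calibration plot of a case-mix model
#'
#' Mean observed outcome against mean predicted outcome over the
#' equally-sized prediction groups, with the identity line.
#'
#' @param fit A `casemix_fit`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(fit) {
  stopifnot(inherits(fit, "casemix_fit"))
  tab <- fit$metrics$calibration_table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$mean_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean predicted", y = "mean observed",
                  title = sprintf("Calibration (%s model, %d groups)",
                                  fit$outcome, nrow(tab))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_indicator_pair
#' @param object An `indicator_table` (for `autoplot`).
#' @param ... Passed on to [plot_indicator_pair()].
#' @method autoplot indicator_table
#' @export
autoplot.indicator_table <- function(object, ...) {
  plot_indicator_pair(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
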