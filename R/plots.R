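# Plot methods: per-scenario frequency distributions and the
# across-scenario summary of geometric means with certainty intervals.

#' Frequency-distribution plot of a simulation
#'
#' Histogram of the adjusted odds ratio (with the observed odds ratio as a
#' dashed reference line) or of the error factor (reference line at the
#' no-bias value 1).
#'
#' @param object An `ltf_simulation`.
#' @param what `"or"` or `"epsilon"`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltf_simulation <- function(object, what = c("or", "epsilon"),
                                    bins = 50L, ...) {
  what <- match.arg(what)
  h <- simulation_histogram(object, what, bins)
  ref <- switch(what, or = object$or_observed, epsilon = 1)
  xlab <- switch(what, or = "Adjusted odds ratio",
                 epsilon = "Error factor (observed OR / adjusted OR)")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = h$upper - h$lower, fill = "grey35") +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::labs(
      x = xlab, y = "Trials",
      title = sprintf("Scenario %s (%d trials)", object$scenario$name,
                      object$n_trials)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Across-scenario summary plot
#'
#' Geometric mean adjusted odds ratios (or error factors) with their
#' certainty intervals, one point-range per scenario; the dashed line
#' marks the observed odds ratio (or 1 for the error factor).
#'
#' @param summary Tibble from [scenario_summary()].
#' @param what `"or"` or `"epsilon"`.
#' @return A ggplot object.
#' @export
plot_scenario_summary <- function(summary, what = c("or", "epsilon")) {
  what <- match.arg(what)
  cols <- switch(what,
                 or = c("gm_or", "or_lower", "or_upper"),
                 epsilon = c("gm_epsilon", "epsilon_lower", "epsilon_upper"))
  ref <- switch(what, or = summary$or_observed[[1L]], epsilon = 1)
  ylab <- switch(what, or = "Geometric mean adjusted OR",
                 epsilon = "Geometric mean error factor")
  ggplot2::ggplot(summary, ggplot2::aes(
    x = factor(.data$scenario, levels = .data$scenario),
    y = .data[[cols[[1L]]]],
    ymin = .data[[cols[[2L]]]],
    ymax = .data[[cols[[3L]]]])) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = "Scenario", y = ylab) +
    ggplot2::theme_minimal()
}
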