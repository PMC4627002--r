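# Reducing a simulation to reported quantities: geometric means, empirical
# certainty intervals, interval widths and binned frequency distributions.

#' Geometric mean of positive values
#'
#' `exp(mean(log(x)))` — the central-tendency summary used for ratio-scale
#' simulation outputs.
#'
#' @param x Non-empty numeric vector of strictly positive values.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x) {
  if (!length(x)) {
    abort("Cannot take the geometric mean of an empty vector.",
          class = "ltfbias_input_error")
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Geometric mean requires positive values; offending indices: %s%s.",
      paste(head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else ""),
      class = "ltfbias_input_error")
  }
  exp(mean(log(x)))
}

#' Empirical certainty interval
#'
#' Central empirical quantile interval of a Monte Carlo distribution: the
#' `(1 - level)/2` and `1 - (1 - level)/2` sample quantiles, computed with
#' linear interpolation between order statistics (`quantile()` type 7).
#' Its interpretation is that of a bias-analysis certainty interval, not a
#' confidence interval.
#'
#' @param values Non-empty numeric vector.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
certainty_interval <- function(values, level = 0.95) {
  if (!length(values)) {
    abort("Cannot summarise an empty vector.", class = "ltfbias_input_error")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).",
          class = "ltfbias_input_error")
  }
  q <- quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  c(lower = q[[1L]], upper = q[[2L]])
}

#' Width of an interval
#'
#' @param ci Numeric vector `c(lower, upper)` with `lower <= upper`.
#' @return `upper - lower`.
#' @export
interval_width <- function(ci) {
  if (length(ci) != 2L || anyNA(ci) || ci[[1L]] > ci[[2L]]) {
    abort("`ci` must be c(lower, upper) with lower <= upper.",
          class = "ltfbias_input_error")
  }
  ci[[2L]] - ci[[1L]]
}

valid_trials <- function(x) {
  tr <- x$trials
  if (any(tr$cell_zero)) tr <- tr[!tr$cell_zero, , drop = FALSE]
  tr
}

#' @rdname run_simulation
#' @param x An `ltf_simulation`.
#' @param ... Unused.
#' @export
tidy.ltf_simulation <- function(x, ...) {
  x$trials
}

#' One-row summary of a bias-analysis simulation
#'
#' Geometric means and certainty intervals of the adjusted odds ratio and
#' of the error factor, mirroring a scenario's row in the results table.
#'
#' @param x An `ltf_simulation` from [run_simulation()].
#' @param level Certainty-interval coverage (default 0.95).
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.ltf_simulation <- function(x, level = 0.95, ...) {
  tr <- valid_trials(x)
  ci_or <- certainty_interval(tr$or_adjusted, level)
  ci_eps <- certainty_interval(tr$epsilon, level)
  tibble(
    scenario = x$scenario$name,
    n_trials = x$n_trials,
    or_observed = x$or_observed,
    gm_epsilon = geometric_mean(tr$epsilon),
    epsilon_lower = ci_eps[["lower"]],
    epsilon_upper = ci_eps[["upper"]],
    gm_or = geometric_mean(tr$or_adjusted),
    or_lower = ci_or[["lower"]],
    or_upper = ci_or[["upper"]],
    or_width = interval_width(ci_or),
    level = level
  )
}

#' Summarise a batch of scenario simulations
#'
#' @param sims List of `ltf_simulation` objects from [run_scenarios()].
#' @inheritParams glance.ltf_simulation
#' @return Tibble with one row per scenario, in input order.
#' @export
scenario_summary <- function(sims, level = 0.95) {
  purrr::map_dfr(sims, glance, level = level)
}

#' Binned frequency distribution of a simulation output
#'
#' Equal-width bins over the sample range, exported with their edges so
#' frequency plots can be rebuilt downstream.
#'
#' @param x An `ltf_simulation`.
#' @param what `"or"` (adjusted odds ratio) or `"epsilon"` (error factor).
#' @param bins Number of equal-width bins (default 50).
#' @return Tibble with `lower`, `upper`, `midpoint`, `count`.
#' @export
simulation_histogram <- function(x, what = c("or", "epsilon"), bins = 50L) {
  what <- match.arg(what)
  values <- switch(what, or = valid_trials(x)$or_adjusted,
                   epsilon = valid_trials(x)$epsilon)
  bins <- check_count(bins, "bins", allow_zero = FALSE)
  rng <- range(values)
  if (rng[[1L]] == rng[[2L]]) {
    return(tibble(lower = rng[[1L]], upper = rng[[2L]],
                  midpoint = rng[[1L]], count = length(values)))
  }
  edges <- seq(rng[[1L]], rng[[2L]], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tibble(
    lower = edges[-length(edges)],
    upper = edges[-1L],
    midpoint = (edges[-length(edges)] + edges[-1L]) / 2,
    count = tabulate(idx, nbins = bins)
  )
}

#' Write a scenario summary table as tab-separated text
#'
#' @param summary Tibble from [scenario_summary()] (or a single
#'   [glance()] row).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  write.table(as.data.frame(summary), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write full structured results as JSON
#'
#' Per scenario: the summary row plus the binned frequency distributions
#' of the adjusted odds ratio and the error factor.
#'
#' @inheritParams scenario_summary
#' @param path Output path.
#' @param bins Histogram bins per distribution.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(sims, path, level = 0.95, bins = 50L) {
  payload <- purrr::map(sims, function(s) {
    list(
      summary = as.list(glance(s, level = level)),
      histogram_or = as.list(simulation_histogram(s, "or", bins)),
      histogram_epsilon = as.list(simulation_histogram(s, "epsilon", bins))
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-trial audit records as tab-separated text
#'
#' One row per trial: the four chain draws, the adjusted cell counts, the
#' adjusted odds ratio and the error factor.
#'
#' @param x An `ltf_simulation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_audit <- function(x, path) {
  write.table(as.data.frame(x$trials), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
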