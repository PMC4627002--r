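# The four-stage sampling chain and the Monte Carlo adjustment engine.
#
# Per trial: (1) AD, the all-cause deaths among losses, from the truncated
# negative binomial; (2) ID, the cause-specific deaths, from an integer
# PERT on [0, AD] with mode cause_proportion * AD; (3) ID_never, the share
# allocated to the reference stratum, from a PERT on [0, ID] with mode
# never_fraction * ID; (4) ID_high, the share of the remaining
# "ever-exposed" deaths allocated to the highest-exposure stratum, from a
# PERT on [0, min(ID_ever, cap)] with mode min(high_fraction * ID_ever,
# cap). A zero drawn at any stage forces every downstream value in that
# trial to zero (zero-propagation); such trials are retained, never
# discarded. Supports are nested: each stage's maximum is the previous
# stage's drawn value.

bind_scenario <- function(scn, table, exposed_label) {
  stopifnot(inherits(scn, "scenario"), inherits(table, "cohort_table"))
  if (nrow(table) < 3) {
    abort("The allocation chain needs at least three strata (reference, middle, highest).",
          class = "ltfbias_input_error")
  }
  exposed <- stratum_row(table, exposed_label)
  ref <- stratum_row(table, reference_label(table))
  if (scn$high_cap > exposed$alive_noncases) {
    abort_config(sprintf(
      "Scenario \"%s\": high_cap (%d) exceeds the living non-cases of stratum \"%s\" (%d).",
      scn$name, scn$high_cap, exposed_label, exposed$alive_noncases))
  }
  list(exposed = exposed, ref = ref,
       high_cap = scn$high_cap,
       never_cap = ref$alive_noncases)  # defensive; inactive when n_lost < alive ref
}

# Vectorized chain: draws all n trials stage by stage under the current
# RNG state. Conditional stages consume randomness only for trials still
# live, so the stream layout is a fixed function of the stage-1 draws.
sim_draws <- function(scn, binding, n) {
  ad <- sample_trunc_negbin(scn$allcause, n)

  id_total <- integer(n)
  live <- ad > 0L
  if (any(live)) {
    id_total[live] <- as.integer(trunc(rpert(
      sum(live), 0, scn$cause_proportion * ad[live], as.numeric(ad[live]))))
  }

  id_never <- integer(n)
  live <- id_total > 0L
  if (any(live)) {
    nmax <- pmin(as.numeric(id_total[live]), binding$never_cap)
    id_never[live] <- as.integer(trunc(rpert(
      sum(live), 0, pmin(scn$never_fraction * id_total[live], nmax), nmax)))
  }

  id_ever <- id_total - id_never
  id_high <- integer(n)
  live <- id_ever > 0L
  if (any(live)) {
    hmax <- pmin(as.numeric(id_ever[live]), binding$high_cap)
    id_high[live] <- as.integer(trunc(rpert(
      sum(live), 0, pmin(scn$high_fraction * id_ever[live], hmax), hmax)))
  }

  tibble(trial = seq_len(n), ad = ad, id_total = id_total,
         id_never = id_never, id_ever = id_ever, id_high = id_high,
         id_middle = id_ever - id_high)
}

#' Draw one Monte Carlo trial of the misclassification chain
#'
#' Runs the four-stage chain once against the current RNG state. Mostly a
#' building block for inspection and testing; [run_simulation()] executes
#' the full seeded run.
#'
#' @param scn A [scenario()].
#' @param table A [cohort_table()] with at least three strata.
#' @param exposed_label Highest-exposure stratum; defaults to the last
#'   stratum.
#' @return A one-row tibble with `ad`, `id_total`, `id_never`, `id_ever`,
#'   `id_high` and the bookkeeping residual `id_middle`.
#' @export
draw_trial <- function(scn, table, exposed_label = highest_label(table)) {
  binding <- bind_scenario(scn, table, exposed_label)
  sim_draws(scn, binding, 1L)
}

#' Mode chain for a worked example
#'
#' Propagates the likeliest (modal) value through the sampling chain
#' without randomness: given the all-cause death count `ad`, reports each
#' stage's continuous PERT mode and the integer value obtained by dropping
#' its decimal portion, which seeds the next stage.
#'
#' @inheritParams draw_trial
#' @param ad All-cause death count to condition on (e.g. the all-cause
#'   distribution's peak).
#' @return Tibble with columns `stage`, `mode` (continuous) and `value`
#'   (integer passed downstream).
#' @export
chain_modes <- function(scn, table, ad, exposed_label = highest_label(table)) {
  binding <- bind_scenario(scn, table, exposed_label)
  id_mode <- scn$cause_proportion * ad
  id <- trunc(id_mode)
  never_mode <- min(scn$never_fraction * id, binding$never_cap)
  nev <- trunc(never_mode)
  ever <- id - nev
  high_mode <- min(scn$high_fraction * ever, binding$high_cap)
  tibble(
    stage = c("id_total", "id_never", "id_ever", "id_high"),
    mode = c(id_mode, never_mode, ever, high_mode),
    value = as.integer(c(id, nev, ever, trunc(high_mode)))
  )
}

#' Adjust the 2x2 table for one (or many) trial draws
#'
#' Subjects drawn as misclassified move from "living non-case" to "case"
#' within their own stratum, so each stratum's row total is conserved:
#' `a = cases_e + id_high`, `b = noncases_e - id_high`,
#' `c = cases_ref + id_never`, `d = noncases_ref - id_never`.
#'
#' @inheritParams draw_trial
#' @param draws Data frame with columns `id_high` and `id_never` (one row
#'   per trial), e.g. from [draw_trial()].
#' @return Tibble with columns `cases_exposed`, `noncases_exposed`,
#'   `cases_reference`, `noncases_reference`.
#' @export
adjust_counts <- function(table, draws, exposed_label = highest_label(table)) {
  e <- stratum_row(table, exposed_label)
  r <- stratum_row(table, reference_label(table))
  id_high <- draws$id_high
  id_never <- draws$id_never
  if (any(id_high < 0L) || any(id_never < 0L)) {
    abort("Misclassification counts must be non-negative.",
          class = "ltfbias_invariant_violation")
  }
  if (any(id_high > e$alive_noncases) || any(id_never > r$alive_noncases)) {
    abort("A reallocation exceeds the living non-case count of its stratum.",
          class = "ltfbias_invariant_violation")
  }
  tibble(
    cases_exposed = e$cases + id_high,
    noncases_exposed = noncases(table, exposed_label) - id_high,
    cases_reference = r$cases + id_never,
    noncases_reference = noncases(table, reference_label(table)) - id_never
  )
}

#' Disease-misclassification error factor
#'
#' The multiplicative error that converts the adjusted odds ratio back
#' into the observed one: `or_observed / or_adjusted`. Values above 1 mean
#' the crude estimate overstates the adjusted association; below 1, that
#' it understates it.
#'
#' @param or_observed,or_adjusted Positive odds ratios (vectorized).
#' @return `or_observed / or_adjusted`.
#' @export
error_factor <- function(or_observed, or_adjusted) {
  if (any(!is.finite(or_observed) | or_observed <= 0) ||
      any(!is.finite(or_adjusted) | or_adjusted <= 0)) {
    abort("Odds ratios must be positive and finite.",
          class = "ltfbias_input_error")
  }
  or_observed / or_adjusted
}

#' Run the Monte Carlo bias-analysis simulation for one scenario
#'
#' Executes `n_trials` independent trials of the sampling chain under a
#' single seeded random stream, converts each draw into an adjusted 2x2
#' table, an adjusted odds ratio and an error factor, and records every
#' trial. Identical `(scenario, table, seed)` triples reproduce identical
#' results. Trials whose adjusted table contains a zero cell (impossible
#' for the bundled cohort, where the post-cap minimum cell is 36) are
#' flagged with `or_adjusted = NA` and a warning, never dropped silently.
#'
#' @inheritParams draw_trial
#' @param n_trials Number of trials; defaults to the scenario's own count.
#' @param seed Integer seed; defaults to the scenario's `seed` field. When
#'   both are `NULL` the current RNG state is used.
#' @return An `ltf_simulation` object: the trial tibble plus the observed
#'   odds ratio and run metadata. See [tidy()] and [glance()] methods.
#' @export
run_simulation <- function(scn, table, n_trials = NULL, seed = NULL,
                           exposed_label = highest_label(table)) {
  binding <- bind_scenario(scn, table, exposed_label)
  n_trials <- check_count(n_trials %||% scn$n_trials, "n_trials",
                          allow_zero = FALSE)
  seed <- seed %||% scn$seed
  draws <- if (is.null(seed)) {
    sim_draws(scn, binding, n_trials)
  } else {
    withr::with_seed(as.integer(seed), sim_draws(scn, binding, n_trials))
  }
  adj <- adjust_counts(table, draws, exposed_label)
  or_observed <- crude_odds_ratio(table, exposed_label)
  cell_zero <- adj$cases_exposed == 0L | adj$noncases_exposed == 0L |
    adj$cases_reference == 0L | adj$noncases_reference == 0L
  or_adjusted <- ifelse(
    cell_zero, NA_real_,
    (adj$cases_exposed / adj$noncases_exposed) /
      (adj$cases_reference / adj$noncases_reference))
  if (any(cell_zero)) {
    warn(sprintf("%d trial(s) produced a zero cell; flagged with NA adjusted OR.",
                 sum(cell_zero)))
  }
  trials <- dplyr::bind_cols(draws, adj)
  trials$or_adjusted <- or_adjusted
  trials$epsilon <- or_observed / or_adjusted
  trials$cell_zero <- cell_zero
  structure(list(
    scenario = scn,
    trials = trials,
    or_observed = or_observed,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_trials = n_trials,
    exposed_label = exposed_label,
    reference_label = reference_label(table)
  ), class = "ltf_simulation")
}

#' @export
print.ltf_simulation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "Bias-analysis simulation: scenario \"%s\", %d trials (seed %s)\n",
    "  observed OR: %.4f  (%s vs %s)\n",
    "  GM adjusted OR: %.3f  [%.3f, %.3f]\n",
    "  GM error factor: %.3f  [%.3f, %.3f]\n"),
    x$scenario$name, x$n_trials,
    if (is.na(x$seed)) "unset" else x$seed,
    x$or_observed, x$exposed_label, x$reference_label,
    g$gm_or, g$or_lower, g$or_upper,
    g$gm_epsilon, g$epsilon_lower, g$epsilon_upper))
  invisible(x)
}

#' Run several scenarios against one cohort table
#'
#' Maps [run_simulation()] over a list of scenarios. When `seed` is given,
#' scenario `i` runs with seed `seed + i`, so a whole batch is reproduced
#' from one integer.
#'
#' @param scenarios List of [scenario()] objects (e.g.
#'   [mcbride_scenarios()]).
#' @inheritParams run_simulation
#' @return Named list of `ltf_simulation` objects.
#' @export
run_scenarios <- function(scenarios, table, n_trials = NULL, seed = NULL,
                          exposed_label = highest_label(table)) {
  sims <- purrr::imap(unname(scenarios), function(scn, i) {
    run_simulation(scn, table, n_trials = n_trials,
                   seed = if (is.null(seed)) NULL else seed + i,
                   exposed_label = exposed_label)
  })
  names(sims) <- purrr::map_chr(scenarios, "name")
  sims
}
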