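# Synthetic cohort generator for property tests and examples on
# non-fixture data.

#' Generate a random valid cohort table
#'
#' Draws a cohort with positive cell counts in every stratum and a
#' loss-to-follow-up total of roughly 15-25% of the cohort, the order of
#' magnitude typical of historical occupational cohorts. The first stratum
#' is the reference; the last is the highest-exposure stratum. Cell-count
#' magnitudes mimic an occupational mortality table: tens of cases and
#' hundreds of non-cases per stratum.
#'
#' @param n_strata Number of exposure strata (>= 2; the full simulation
#'   chain additionally requires >= 3).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A [cohort_table()].
#' @export
generate_synthetic_table <- function(n_strata = 3L, seed = NULL) {
  n_strata <- check_count(n_strata, "n_strata", allow_zero = FALSE)
  if (n_strata < 2L) {
    abort("`n_strata` must be at least 2.", class = "ltfbias_input_error")
  }
  gen <- function() {
    labels <- c("never-exposed",
                if (n_strata > 2L) sprintf("level-%d", seq_len(n_strata - 2L)),
                "highest-exposed")
    strata <- tibble(
      label = labels,
      cases = sample(3:60, n_strata, replace = TRUE),
      alive_noncases = sample(80:900, n_strata, replace = TRUE),
      deceased_other = sample(5:120, n_strata, replace = TRUE)
    )
    cohort <- sum(strata$cases) + sum(strata$alive_noncases) +
      sum(strata$deceased_other)
    cohort_table(strata,
                 n_lost = round(cohort * runif(1, 0.15, 0.25)),
                 reference = "never-exposed")
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
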