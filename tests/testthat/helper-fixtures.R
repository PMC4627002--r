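# Shared fixtures, built in code.

fixture_table <- function() mcbride_cohort()

fixture_scenarios <- function() mcbride_scenarios()

# A two-stratum toy table for crude-measure edge cases.
toy_table <- function(a = 1, b_alive = 1, b_dec = 0,
                      c = 1, d_alive = 2, d_dec = 0) {
  cohort_table(
    data.frame(
      label = c("ref", "exp"),
      cases = c(c, a),
      alive_noncases = c(d_alive, b_alive),
      deceased_other = c(d_dec, b_dec)
    ),
    n_lost = 10, reference = "ref"
  )
}

# A one-point all-cause law at 0: the fully degenerate scenario in which
# zero-propagation zeroes the whole chain every trial.
null_scenario <- function(n_trials = 200L) {
  scenario(
    name = "null",
    allcause = trunc_negbin_spec(prob = 0.5, size = 1, lower = 0, upper = 0),
    cause_proportion = 0.204,
    direction = "A",
    high_cap = 112,
    n_trials = n_trials
  )
}

# Enumerated pmf of the renormalized truncated negative binomial: the
# brute-force oracle used against the sampler.
enum_trunc_negbin <- function(prob, size, lower, upper) {
  p <- dnbinom(lower:upper, size = size, prob = prob)
  p / sum(p)
}
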