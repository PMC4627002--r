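# The two sampling laws of the bias model: a renormalized truncated
# negative binomial for the all-cause death count among losses, and an
# integer-truncated BetaPERT for every downstream allocation step.

#' Specify a truncated negative binomial distribution
#'
#' The negative binomial is parameterized as the number of failures before
#' the `size`-th success with success probability `prob` (support starting
#' at 0), then conditioned on lying in `[lower, upper]`. Conditioning
#' renormalizes the probability mass; it never clamps draws to the bounds.
#'
#' @param prob Success probability, strictly inside (0, 1).
#' @param size Positive integer shape (number of successes).
#' @param lower,upper Inclusive integer truncation bounds, `lower <= upper`.
#' @return A `trunc_negbin_spec` object.
#' @export
trunc_negbin_spec <- function(prob, size, lower = 0L, upper) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    abort("`prob` must be a single number strictly inside (0, 1).",
          class = "ltfbias_invalid_spec")
  }
  size <- check_count(size, "size", allow_zero = FALSE)
  lower <- check_count(lower, "lower")
  upper <- check_count(upper, "upper")
  if (lower > upper) {
    abort("`lower` must not exceed `upper`.", class = "ltfbias_invalid_spec")
  }
  structure(list(prob = prob, size = size, lower = lower, upper = upper),
            class = "trunc_negbin_spec")
}

#' @export
print.trunc_negbin_spec <- function(x, ...) {
  cat(sprintf("Truncated negative binomial: prob = %g, size = %d, support [%d, %d]\n",
              x$prob, x$size, x$lower, x$upper))
  invisible(x)
}

#' Sample from a truncated negative binomial
#'
#' Draws via the inverse-CDF of the renormalized truncated law: a uniform
#' variate is placed between the parent CDF evaluated just below `lower`
#' and at `upper`, then mapped back through the parent quantile function.
#'
#' @param spec A [trunc_negbin_spec()].
#' @param n Number of draws.
#' @return Integer vector of length `n`, every element in
#'   `[spec$lower, spec$upper]`.
#' @export
sample_trunc_negbin <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "trunc_negbin_spec"))
  f_lo <- if (spec$lower > 0L) {
    pnbinom(spec$lower - 1L, size = spec$size, prob = spec$prob)
  } else {
    0
  }
  f_hi <- pnbinom(spec$upper, size = spec$size, prob = spec$prob)
  if (f_hi <= f_lo) {
    abort("The truncated support carries no probability mass.",
          class = "ltfbias_invalid_spec")
  }
  as.integer(qnbinom(runif(n, f_lo, f_hi), size = spec$size, prob = spec$prob))
}

#' Fit a truncated negative binomial to a stated likeliest count
#'
#' Expert-opinion inputs for the all-cause death count among losses come as
#' (minimum, likeliest, maximum); the negative binomial is parameterized by
#' (probability, shape) instead. This fitter searches shape over a small
#' integer grid and probability over a fine grid, returning the spec whose
#' mode on the truncated support is closest to `likeliest`. The truncated
#' mode is the parent mode, `floor((size - 1) (1 - prob) / prob)`, clamped
#' to the bounds (the parent pmf is unimodal). Ties are broken toward
#' smaller shape, then toward the probability whose continuous parent mode
#' is closest to `likeliest`, then toward larger probability (the most
#' concentrated candidate).
#'
#' @param likeliest Target mode (whole, within the bounds).
#' @param lower,upper Truncation bounds.
#' @param max_size Largest shape considered.
#' @param prob_step Probability grid resolution.
#' @return A [trunc_negbin_spec()].
#' @export
fit_negbin_from_mode <- function(likeliest, lower = 0L, upper,
                                 max_size = 8L, prob_step = 1e-4) {
  likeliest <- check_count(likeliest, "likeliest")
  lower <- check_count(lower, "lower")
  upper <- check_count(upper, "upper")
  if (likeliest < lower || likeliest > upper) {
    abort("`likeliest` must lie within [lower, upper].",
          class = "ltfbias_invalid_spec")
  }
  grid <- expand.grid(size = seq_len(max_size),
                      prob = seq(prob_step, 1 - prob_step, by = prob_step))
  cont_mode <- ifelse(grid$size == 1L, 0,
                      (grid$size - 1) * (1 - grid$prob) / grid$prob)
  trunc_mode <- pmin(pmax(floor(cont_mode), lower), upper)
  ord <- order(abs(trunc_mode - likeliest),        # closest truncated mode
               grid$size,                          # then smaller shape
               abs(cont_mode - likeliest),         # then closest parent mode
               -grid$prob)                         # then most concentrated
  best <- ord[[1L]]
  trunc_negbin_spec(prob = grid$prob[[best]], size = grid$size[[best]],
                    lower = lower, upper = upper)
}

#' Specify a BetaPERT distribution
#'
#' The PERT law is a beta distribution re-parameterized by minimum,
#' likeliest (mode) and maximum, with shape weight `lambda`; the classic
#' PERT uses `lambda = 4`. It is the standard smooth alternative to the
#' triangular distribution for encoding expert opinion.
#'
#' @param minimum,mode,maximum Real parameters with
#'   `minimum <= mode <= maximum`.
#' @param lambda Positive shape weight (default 4).
#' @return A `pert_spec` object.
#' @export
pert_spec <- function(minimum, mode, maximum, lambda = 4) {
  if (!all(is.finite(c(minimum, mode, maximum, lambda)))) {
    abort("PERT parameters must be finite.", class = "ltfbias_invalid_spec")
  }
  if (minimum > mode || mode > maximum) {
    abort("PERT requires minimum <= mode <= maximum.",
          class = "ltfbias_invalid_spec")
  }
  if (lambda <= 0) {
    abort("`lambda` must be positive.", class = "ltfbias_invalid_spec")
  }
  structure(list(minimum = minimum, mode = mode, maximum = maximum,
                 lambda = lambda),
            class = "pert_spec")
}

#' @export
print.pert_spec <- function(x, ...) {
  cat(sprintf("BetaPERT: min = %g, mode = %g, max = %g, lambda = %g\n",
              x$minimum, x$mode, x$maximum, x$lambda))
  invisible(x)
}

# Vectorized continuous PERT sampler. All parameter vectors are recycled to
# length n; degenerate ranges (max == min) return the point mass at min.
rpert <- function(n, minimum, mode, maximum, lambda = 4) {
  minimum <- rep_len(minimum, n)
  mode <- rep_len(mode, n)
  maximum <- rep_len(maximum, n)
  lambda <- rep_len(lambda, n)
  out <- minimum
  live <- maximum > minimum
  if (any(live)) {
    rng <- maximum[live] - minimum[live]
    alpha <- 1 + lambda[live] * (mode[live] - minimum[live]) / rng
    beta <- 1 + lambda[live] * (maximum[live] - mode[live]) / rng
    out[live] <- minimum[live] + rng * rbeta(sum(live), alpha, beta)
  }
  out
}

#' Sample integer counts from a BetaPERT distribution
#'
#' Draws the continuous PERT variate, then truncates toward zero to an
#' integer (the decimal portion is dropped, never rounded); a degenerate
#' spec with `maximum == minimum` returns `trunc(minimum)` every time.
#'
#' @param spec A [pert_spec()].
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_pert_int <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "pert_spec"))
  as.integer(trunc(rpert(n, spec$minimum, spec$mode, spec$maximum, spec$lambda)))
}
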