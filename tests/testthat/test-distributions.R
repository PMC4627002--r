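test_that("truncated negative binomial draws stay in-support and match the pmf oracle", {
  spec <- trunc_negbin_spec(prob = 0.02, size = 3, lower = 0, upper = 338)
  withr::with_seed(101, {
    x <- sample_trunc_negbin(spec, 1e6)
    expect_true(all(x >= 0 & x <= 338))
    pm <- enum_trunc_negbin(0.02, 3, 0, 338)
    emp <- tabulate(x + 1L, nbins = 339L) / length(x)
    # the empirical mode must be a near-modal support point of the
    # enumerated truncated pmf (the pmf is nearly flat around its peak)
    analytic_mode <- which.max(pm) - 1L
    # (size - 1)(1 - p)/p = 98 exactly, so the pmf ties at 97 and 98; the
    # enumerated argmax is the first of the tied pair and lies in-support
    expect_equal(pm[98], pm[99])
    expect_lte(abs(analytic_mode - 98L), 1L)
    emp_mode <- which.max(emp) - 1L
    expect_lte(abs(emp_mode - analytic_mode), 5L)
    expect_gte(pm[emp_mode + 1L], 0.999 * max(pm))
  })
})

test_that("truncated negative binomial mean matches enumeration within 3 SE", {
  spec <- trunc_negbin_spec(prob = 0.027, size = 2, lower = 0, upper = 338)
  pm <- enum_trunc_negbin(0.027, 2, 0, 338)
  mu <- sum((0:338) * pm)
  sdv <- sqrt(sum((0:338)^2 * pm) - mu^2)
  withr::with_seed(102, {
    x <- sample_trunc_negbin(spec, 1e6)
    expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(length(x)))
  })
})

test_that("truncation conditions and renormalizes rather than clamping", {
  # a one-point support always returns that point
  point <- trunc_negbin_spec(prob = 0.1, size = 2, lower = 7, upper = 7)
  expect_identical(unique(sample_trunc_negbin(point, 500)), 7L)
  # clamping would pile mass on the upper bound; conditioning must not
  spec <- trunc_negbin_spec(prob = 0.02, size = 3, lower = 0, upper = 100)
  withr::with_seed(103, {
    x <- sample_trunc_negbin(spec, 2e5)
    pm <- enum_trunc_negbin(0.02, 3, 0, 100)
    expect_lt(mean(x == 100), pm[101] + 4 * sqrt(pm[101] / 2e5) + 1e-3)
  })
})

test_that("impossible truncated supports are rejected", {
  expect_error(trunc_negbin_spec(prob = 0, size = 3, lower = 0, upper = 10),
               class = "ltfbias_invalid_spec")
  expect_error(trunc_negbin_spec(prob = 0.5, size = 3, lower = 5, upper = 2),
               class = "ltfbias_invalid_spec")
  # support so deep in the tail that it carries no numeric mass
  far <- trunc_negbin_spec(prob = 0.999, size = 1, lower = 300, upper = 338)
  expect_error(sample_trunc_negbin(far, 10), class = "ltfbias_invalid_spec")
})

test_that("mode-based fitting recovers the stated likeliest counts", {
  # enumeration oracle for the truncated mode of a fitted spec
  trunc_mode <- function(s) {
    which.max(enum_trunc_negbin(s$prob, s$size, s$lower, s$upper)) - 1L + s$lower
  }
  f104 <- fit_negbin_from_mode(104, 0, 338)
  expect_lte(abs(trunc_mode(f104) - 104L), 6L)
  f37 <- fit_negbin_from_mode(37, 0, 338)
  expect_lte(abs(trunc_mode(f37) - 37L), 2L)
  f0 <- fit_negbin_from_mode(0, 0, 338)
  expect_identical(trunc_mode(f0), 0L)
  expect_identical(f0$size, 1L)
  expect_error(fit_negbin_from_mode(400, 0, 338), class = "ltfbias_invalid_spec")
})

test_that("PERT pre-truncation mean matches its closed form", {
  # E[X] = (min + lambda * mode + max) / (lambda + 2) for the classic
  # lambda = 4 parameterization
  withr::with_seed(104, {
    x <- ltfbias:::rpert(1e6, 0, 21.2, 104)
    mu <- (0 + 4 * 21.2 + 104) / 6
    alpha <- 1 + 4 * 21.2 / 104
    beta <- 1 + 4 * (104 - 21.2) / 104
    sdv <- 104 * sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)))
    expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(length(x)))
  })
})

test_that("integer PERT draws respect bounds, truncate toward zero and match bin probabilities", {
  expect_identical(unique(sample_pert_int(pert_spec(0, 0, 0), 200)), 0L)
  spec <- pert_spec(0, 15.75, 21)
  withr::with_seed(105, {
    x <- sample_pert_int(spec, 2e5)
    expect_true(all(x %in% 0:21))
    # oracle: integrate the underlying beta density over unit bins
    alpha <- 1 + 4 * 15.75 / 21
    beta <- 1 + 4 * (21 - 15.75) / 21
    probs <- pbeta((1:21) / 21, alpha, beta) - pbeta((0:20) / 21, alpha, beta)
    # bin 21 has probability zero (only the single point x = 21)
    counts <- tabulate(x + 1L, nbins = 21L)
    gof <- suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs)))
    expect_gt(gof$p.value, 1e-4)
  })
})

test_that("PERT approaches the uniform law as lambda tends to zero", {
  withr::with_seed(106, {
    x <- ltfbias:::rpert(2e5, 10, 12, 30, lambda = 1e-6)
    expect_lt(abs(mean(x) - 20), 3 * (30 - 10) / sqrt(12) / sqrt(2e5))
  })
})

test_that("PERT specs validate their ordering and shape weight", {
  expect_error(pert_spec(0, 5, 4), class = "ltfbias_invalid_spec")
  expect_error(pert_spec(3, 2, 4), class = "ltfbias_invalid_spec")
  expect_error(pert_spec(0, 1, 2, lambda = 0), class = "ltfbias_invalid_spec")
})
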