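test_that("the bundled cohort table satisfies its published marginals", {
  tab <- fixture_table()
  expect_s3_class(tab, "cohort_table")
  expect_identical(nrow(tab), 3L)
  expect_identical(n_lost(tab), 338L)
  expect_identical(reference_label(tab), "never-exposed")
  expect_identical(highest_label(tab), ">=2085.8 ppt-mo")
  expect_identical(noncases(tab, ">=2085.8 ppt-mo"), 112L + 36L)
  expect_identical(noncases(tab, "never-exposed"), 414L + 37L)
  expect_identical(noncases(tab), c(451L, 925L, 148L))
})

test_that("construction rejects invalid strata", {
  df <- data.frame(label = c("a", "b"), cases = c(1, 2),
                   alive_noncases = c(3, 4), deceased_other = c(5, 6))
  expect_s3_class(cohort_table(df, 1), "cohort_table")
  expect_error(cohort_table(df[1, ], 1), class = "ltfbias_input_error")
  expect_error(cohort_table(transform(df, cases = c(1.5, 2)), 1),
               class = "ltfbias_input_error")
  expect_error(cohort_table(transform(df, cases = c(-1, 2)), 1),
               class = "ltfbias_input_error")
  expect_error(cohort_table(df, -1), class = "ltfbias_input_error")
  expect_error(cohort_table(df, 1, reference = "zzz"),
               class = "ltfbias_input_error")
  expect_error(cohort_table(rbind(df, df), 1), class = "ltfbias_input_error")
})

test_that("crude odds match the published per-stratum values", {
  tab <- fixture_table()
  expect_equal(crude_odds(tab, ">=2085.8 ppt-mo"), 14 / 148)
  expect_equal(round(crude_odds(tab, ">=2085.8 ppt-mo"), 4), 0.0946)
  expect_equal(round(crude_odds(tab, "never-exposed"), 4), 0.0310)
  zero <- toy_table(a = 1, c = 0)
  expect_equal(crude_odds(zero, "ref"), 0)
})

test_that("crude odds ratio reproduces the published estimate and identities", {
  tab <- fixture_table()
  or <- crude_odds_ratio(tab)
  expect_equal(or, (14 / 148) / (14 / 451))
  expect_identical(sprintf("%.2f", or), "3.05")
  # identical strata give the null
  same <- cohort_table(
    data.frame(label = c("r", "e"), cases = c(14, 14),
               alive_noncases = c(112, 112), deceased_other = c(36, 36)),
    n_lost = 0, reference = "r")
  expect_equal(crude_odds_ratio(same, "e"), 1)
  expect_equal(crude_odds_ratio(toy_table(), "exp"), 2)
})

test_that("odds ratio is invariant to scaling all cells by a common factor", {
  tab <- fixture_table()
  for (k in c(2L, 5L, 11L)) {
    scaled <- cohort_table(
      data.frame(label = tab$label, cases = tab$cases * k,
                 alive_noncases = tab$alive_noncases * k,
                 deceased_other = tab$deceased_other * k),
      n_lost = n_lost(tab), reference = reference_label(tab))
    expect_equal(crude_odds_ratio(scaled), crude_odds_ratio(tab))
  }
})

test_that("the Wald interval reproduces the published bounds", {
  tab <- fixture_table()
  ci <- wald_ci(tab, level = 0.95)
  expect_identical(sprintf("%.2f", ci[["lower"]]), "1.42")
  expect_identical(sprintf("%.2f", ci[["upper"]]), "6.54")
})

test_that("Wald interval agrees with an independent hand evaluation at level 0.90", {
  tab <- fixture_table()
  # oracle: direct formula evaluation with z fixed at its 0.90 value
  or <- (14 / 148) / (14 / 451)
  se <- sqrt(1 / 14 + 1 / 148 + 1 / 14 + 1 / 451)
  z <- 1.644854
  ci <- wald_ci(tab, level = 0.90)
  expect_equal(ci[["lower"]], exp(log(or) - z * se), tolerance = 1e-6)
  expect_equal(ci[["upper"]], exp(log(or) + z * se), tolerance = 1e-6)
})

test_that("interval contains the estimate and widens with the level", {
  tab <- fixture_table()
  or <- crude_odds_ratio(tab)
  ci0 <- wald_ci(tab, level = 0)
  expect_equal(unname(ci0), c(or, or))
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(lv) {
    ci <- wald_ci(tab, level = lv)
    expect_lte(ci[["lower"]], or)
    expect_gte(ci[["upper"]], or)
    interval_width(ci)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("zero cells raise the degenerate-table error", {
  degen <- toy_table(a = 0)
  expect_error(crude_odds_ratio(degen, "exp"),
               class = "ltfbias_degenerate_table")
  expect_error(wald_ci(degen, "exp"), class = "ltfbias_degenerate_table")
  no_nc <- toy_table(b_alive = 0, b_dec = 0)
  expect_error(crude_odds(no_nc, "exp"), class = "ltfbias_degenerate_table")
})

test_that("cohort tables round-trip through the delimited-text format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- fixture_table()
  write_cohort_table(tab, path)
  back <- read_cohort_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(n_lost(back), n_lost(tab))
  expect_identical(reference_label(back), reference_label(tab))

  synth <- generate_synthetic_table(4, seed = 11)
  write_cohort_table(synth, path)
  expect_equal(as.data.frame(read_cohort_table(path)), as.data.frame(synth))
})
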