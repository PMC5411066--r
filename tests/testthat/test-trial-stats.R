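test_that("Woolf statistics agree with the textbook oracle on integer tables", {
  cases <- list(c(13, 446, 20, 228), c(45, 4128, 64, 4128),
                c(633, 7891, 715, 7755), c(8, 403, 18, 226))
  for (cs in cases) {
    est <- odds_ratio_ci(two_by_two(cs[1], cs[2], cs[3], cs[4]))
    o <- woolf_oracle(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3])
    expect_equal(est$odds_ratio, o$or, tolerance = 1e-12)
    expect_equal(est$ci_lower, o$lo, tolerance = 1e-12)
    expect_equal(est$ci_upper, o$up, tolerance = 1e-12)
    expect_equal(est$p_value, o$p, tolerance = 1e-12)
    expect_equal(est$relative_risk, (cs[1] / cs[2]) / (cs[3] / cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("fractional expected counts reproduce published model rows", {
  # deficient-cohort design sums at 1000 person-years per arm
  est <- odds_ratio_ci(two_by_two(11.7, 1000, 22.5, 1000))
  expect_equal(round(est$odds_ratio, 2), 0.51)
  expect_equal(round(est$ci_lower, 2), 0.25)
  expect_equal(round(est$ci_upper, 2), 1.05)
  # unequal-arm 3-year totals (266x3 and 403x3 person-years)
  est4 <- odds_ratio_ci(two_by_two(11.9, 1209, 11.1, 798))
  expect_equal(round(est4$odds_ratio, 2), 0.70)
  expect_equal(round(est4$ci_lower, 2), 0.31)
  expect_equal(round(est4$ci_upper, 2), 1.60)
  expect_equal(round(est4$p_value, 2), 0.40)
})

test_that("identical arms give OR 1 and p 1", {
  est <- odds_ratio_ci(two_by_two(12, 500, 12, 500))
  expect_equal(est$odds_ratio, 1)
  expect_equal(est$p_value, 1)
  expect_equal(est$relative_risk, 1)
})

test_that("arm swap maps OR to its reciprocal and mirrors the CI", {
  est <- odds_ratio_ci(two_by_two(11.7, 1000, 22.5, 1000))
  swp <- odds_ratio_ci(two_by_two(22.5, 1000, 11.7, 1000))
  expect_equal(swp$odds_ratio, 1 / est$odds_ratio, tolerance = 1e-12)
  expect_equal(swp$ci_lower, 1 / est$ci_upper, tolerance = 1e-12)
  expect_equal(swp$ci_upper, 1 / est$ci_lower, tolerance = 1e-12)
  expect_equal(swp$p_value, est$p_value, tolerance = 1e-12)
})

test_that("scaling all cells preserves the OR and narrows the CI", {
  base <- odds_ratio_ci(two_by_two(11.7, 1000, 22.5, 1000))
  for (k in c(2, 5, 10)) {
    scl <- odds_ratio_ci(two_by_two(11.7 * k, 1000 * k, 22.5 * k, 1000 * k))
    expect_equal(scl$odds_ratio, base$odds_ratio, tolerance = 1e-12)
    expect_lt(scl$ci_upper - scl$ci_lower, base$ci_upper - base$ci_lower)
  }
})

test_that("p-value and CI are mutually consistent at every alpha", {
  tables <- list(two_by_two(11.7, 1000, 22.5, 1000),
                 two_by_two(93, 10000, 126.5, 10000),
                 two_by_two(12, 500, 13, 500))
  for (tab in tables) {
    for (alpha in c(0.01, 0.05, 0.1, 0.3)) {
      est <- odds_ratio_ci(tab, alpha = alpha)
      outside <- est$ci_lower > 1 || est$ci_upper < 1
      expect_identical(est$p_value < alpha, outside)
      expect_true(est$ci_lower <= est$odds_ratio)
      expect_true(est$odds_ratio <= est$ci_upper)
    }
  }
})

test_that("the exact normal quantile is used, not 1.96", {
  est <- odds_ratio_ci(two_by_two(50, 1000, 70, 1000))
  lo_exact <- exp(log(est$odds_ratio) - qnorm(0.975) * est$se_log_or)
  expect_equal(est$ci_lower, lo_exact, tolerance = 1e-15)
})

test_that("degenerate tables are rejected", {
  expect_error(two_by_two(-1, 100, 5, 100), "non-negative")
  expect_error(two_by_two(100, 100, 5, 100), "exceed cases")
  expect_error(odds_ratio_ci(two_by_two(0, 100, 5, 100)),
               "continuity correction")
  expect_error(odds_ratio_ci(two_by_two(3, 100, 5, 100), alpha = 1.2),
               "between 0 and 1")
})

test_that("effect estimates render in the conventional string form", {
  est <- odds_ratio_ci(two_by_two(11.7, 1000, 22.5, 1000))
  expect_equal(format(est), "0.51 (0.25–1.05)")
  est4 <- odds_ratio_ci(two_by_two(11.9, 1209, 11.1, 798))
  expect_equal(format(est4, p = TRUE), "0.70 (0.31–1.60, P = 0.40)")
})
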