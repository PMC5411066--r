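test_that("the normalizing mean odds ratio matches direct evaluation", {
  m <- normalizing_mean_or(default_curve, default_pop)
  expect_equal(m, mean(18.3 * default_pop$decile_baselines^-0.833))
  expect_equal(round(m, 3), 1.418)
  # flat curve normalizes to 1; single-decile population to its own OR
  expect_equal(normalizing_mean_or(dose_response_curve(1, 0), default_pop), 1)
  one <- population_distribution(20, label = "single")
  expect_equal(normalizing_mean_or(default_curve, one), 18.3 * 20^-0.833)
  expect_equal(round(normalizing_mean_or(default_curve, one), 3), 1.509)
})

test_that("per-decile expected cases match the spreadsheet oracle", {
  sc <- trial_scenario(dose = 2000, person_years_per_arm = 4000)
  tab <- expected_cases(sc)
  expect_equal(tab$control_cases,
               cases_oracle(sc$cohort_baselines, 400))
  expect_equal(tab$treatment_cases,
               cases_oracle(tab$achieved, 400))
  # totals attribute equals the column sums
  tot <- attr(tab, "totals")
  expect_equal(tot[["control"]], sum(tab$control_cases), tolerance = 1e-9)
  expect_equal(tot[["treatment"]], sum(tab$treatment_cases), tolerance = 1e-9)
  expect_true(all(tab$control_cases >= 0 & tab$treatment_cases >= 0))
})

test_that("verified reference cells reproduce to one decimal", {
  sc <- trial_scenario(dose = 2000, person_years_per_arm = 4000)
  tab <- expected_cases(sc)
  by_base <- function(b) tab$control_cases[tab$baseline == b]
  expect_equal(round(by_base(14), 1), 10.1)
  expect_equal(round(by_base(20), 1), 7.5)
  expect_equal(round(by_base(40), 1), 4.2)
})

test_that("baseline totals conserve the background rate exactly", {
  # with no dose, total expected cases = r * total person-years
  sc <- trial_scenario(dose = 0, person_years_per_arm = 4000)
  tot <- attr(expected_cases(sc), "totals")
  expect_equal(tot[["control"]], 0.0176 * 4000, tolerance = 1e-9)
  expect_equal(tot[["treatment"]], 0.0176 * 4000, tolerance = 1e-9)
})

test_that("a flat curve makes the normalization cancel", {
  sc <- trial_scenario(dose = 2000, person_years_per_arm = 5000,
                       curve = dose_response_curve(1, 0))
  tab <- expected_cases(sc)
  expect_equal(tab$control_cases, rep(0.0176 * 500, 10))
  expect_equal(tab$treatment_cases, rep(0.0176 * 500, 10))
})

test_that("raising the dose never increases any treatment count", {
  prev <- NULL
  for (d in c(0, 400, 1000, 2000, 4000)) {
    sc <- trial_scenario(dose = d, selected_deciles = 2:10)
    cur <- expected_cases(sc)$treatment_cases
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("unequal arms and explicit weights flow through", {
  sc <- trial_scenario(dose = 1000, selected_deciles = 5:9,
                       person_years_per_arm = 798,
                       treatment_person_years = 1209)
  tab <- expected_cases(sc)
  expect_equal(sum(tab$control_person_years), 798)
  expect_equal(sum(tab$treatment_person_years), 1209)
  expect_equal(tab$control_person_years, rep(798 / 5, 5))
  sc_w <- trial_scenario(dose = 2000, selected_deciles = 1:2,
                         person_years_per_arm = 300, weights = c(2, 1))
  expect_equal(expected_cases(sc_w)$control_person_years, c(200, 100))
})

test_that("expected-case tables write to CSV with a total row", {
  sc <- trial_scenario(dose = 2000, selected_deciles = 6:10,
                       person_years_per_arm = 4000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expected_cases(expected_cases(sc), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$control_cases[6], sum(back$control_cases[1:5]),
               tolerance = 1e-9)
})
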