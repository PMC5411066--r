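test_that("population distributions validate their deciles", {
  expect_equal(default_pop$decile_baselines,
               c(11, 14, 17, 20, 23, 26, 29, 33, 36, 40))
  expect_error(population_distribution(numeric(0)), "non-empty")
  expect_error(population_distribution(c(11, 11, 14)), "strictly increasing")
  expect_error(population_distribution(c(0.5, 14)), ">= 1")
})

test_that("scenarios default sensibly and validate inputs", {
  sc <- trial_scenario(dose = 2000)
  expect_equal(sc$incidence_rate, 0.0176)
  expect_equal(sc$alpha, 0.05)
  expect_equal(sc$cohort_baselines, default_pop$decile_baselines)
  expect_equal(sum(sc$weights), 1)
  expect_error(trial_scenario(dose = 2000, selected_deciles = integer(0)),
               "non-empty")
  expect_error(trial_scenario(dose = 2000, incidence_rate = 1.5),
               "between 0 and 1")
  expect_error(trial_scenario(dose = 2000, incidence_rate = 0),
               "between 0 and 1")
  expect_error(trial_scenario(dose = 2000, person_years_per_arm = -5),
               "positive")
  expect_error(trial_scenario(dose = 2000, selected_deciles = c(1, 99)),
               "indices")
  expect_error(trial_scenario(dose = -10), "non-negative")
  expect_error(trial_scenario(dose = 2000, cohort_baselines = 14,
                              achieved_override = 10),
               "below their baselines")
  expect_error(trial_scenario(dose = 2000, weights = c(1, 2)), "one per")
})

test_that("scenario configs round-trip through YAML", {
  sc <- trial_scenario(dose = 2000, selected_deciles = 6:10,
                       person_years_per_arm = 4000,
                       incidence_rate = 0.0176, alpha = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- load_scenario(path, quiet = TRUE)
  for (field in c("dose", "incidence_rate", "alpha", "person_years_per_arm",
                  "treatment_person_years", "cohort_baselines", "weights",
                  "selected_deciles")) {
    expect_equal(back[[field]], sc[[field]], info = field)
  }
  expect_equal(back$population$decile_baselines, sc$population$decile_baselines)
  expect_equal(back$curve$coefficient, sc$curve$coefficient)
  # single-cohort scenarios with overrides also round-trip
  sc2 <- trial_scenario(dose = 2000, cohort_baselines = 14,
                        achieved_override = 34)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc2, path2)
  back2 <- load_scenario(path2, quiet = TRUE)
  expect_equal(back2$cohort_baselines, 14)
  expect_equal(back2$achieved_override, 34)
})

test_that("minimal configs take documented defaults and report them", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("dose: 2000", path)
  expect_message(sc <- load_scenario(path), "defaults applied")
  expect_equal(sc$incidence_rate, 0.0176)
  expect_equal(sc$alpha, 0.05)
  expect_equal(length(sc$cohort_baselines), 10)
  # a rate written as 1760e-5 loads as 0.0176
  writeLines(c("dose: 2000", "incidence_rate: 1760e-5"), path)
  expect_equal(load_scenario(path, quiet = TRUE)$incidence_rate, 0.0176)
  # empty decile list is a validation error
  writeLines(c("dose: 2000", "selected_deciles: []"), path)
  expect_error(load_scenario(path, quiet = TRUE), "non-empty")
  # missing dose and unknown keys are named
  writeLines("alpha: 0.05", path)
  expect_error(load_scenario(path, quiet = TRUE), "dose")
  writeLines(c("dose: 2000", "bogus_key: 1"), path)
  expect_error(load_scenario(path, quiet = TRUE), "bogus_key")
})

test_that("the shipped example scenario loads and matches its preset", {
  path <- system.file("extdata", "scenario_replete_2000iu.yaml",
                      package = "vdrct")
  sc <- load_scenario(path, quiet = TRUE)
  preset <- scenario_preset("table5")
  expect_equal(evaluate_scenario(sc)$odds_ratio,
               evaluate_scenario(preset)$odds_ratio)
})
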