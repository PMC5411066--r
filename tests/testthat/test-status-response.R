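test_that("calibration backend reproduces every grid cell exactly", {
  g <- reference_grid
  for (i in seq_along(g$baselines)) {
    for (j in seq_along(g$doses)) {
      expect_identical(achieved(calib_model, g$baselines[i], g$doses[j]),
                       g$achieved[i, j])
    }
  }
})

test_that("zero dose is the identity under both backends", {
  for (m in list(calib_model, param_model)) {
    expect_equal(achieved(m, 23, 0), 23)
    expect_equal(achieved(m, c(11, 14, 77), 0), c(11, 14, 77))
  }
})

test_that("calibration backend interpolates bilinearly and clamps at edges", {
  # halfway in dose between 1000 (24) and 2000 (33) at baseline 14
  expect_equal(achieved(calib_model, 14, 1500), (24 + 33) / 2)
  # halfway in baseline between 14 (33) and 17 (35) at dose 2000
  expect_equal(achieved(calib_model, 15.5, 2000), 34)
  # below the lowest grid dose: linear from identity at dose 0 to 400 cell
  expect_equal(achieved(calib_model, 14, 200), (14 + 18) / 2)
  # flat clamp beyond the grid
  expect_equal(achieved(calib_model, 14, 8000), achieved(calib_model, 14, 4000))
  expect_equal(achieved(calib_model, 50, 2000), achieved(calib_model, 40, 2000))
  expect_equal(achieved(calib_model, 5, 2000), achieved(calib_model, 11, 2000))
})

test_that("off-grid queries error when interpolation is disabled", {
  expect_error(achieved(calib_model, 14, 1500, interpolate = FALSE),
               "interpolation is disabled")
  expect_error(achieved(calib_model, 15, 2000, interpolate = FALSE),
               "not a calibration grid point")
  # exact grid points still fine
  expect_equal(achieved(calib_model, 14, 2000, interpolate = FALSE), 33)
})

test_that("input validation rejects bad baselines and doses", {
  expect_error(achieved(calib_model, 14, -100), "non-negative")
  expect_error(achieved(calib_model, 0, 2000), "strictly positive")
  expect_error(achieved(calib_model, -3, 0), "strictly positive")
})

test_that("the known non-monotone grid cell is flagged, not corrected", {
  expect_warning(status_response_model(), "anomalies")
  w <- tryCatch(status_response_model(), warning = conditionMessage)
  expect_match(w, "decreases from 25 to 18")
  # the cell itself is stored verbatim
  expect_equal(achieved(calib_model, 11, 400), 25)
  expect_equal(achieved(calib_model, 14, 400), 18)
  # a clean grid produces no warning and an empty anomaly list
  clean <- expand.grid(baseline_ng_ml = c(10, 20), dose_iu_d = c(400, 1000))
  clean$achieved_ng_ml <- clean$baseline_ng_ml + clean$dose_iu_d / 100
  expect_no_warning(status_response_model(calibration = clean))
  expect_length(check_calibration(clean), 0)
})

test_that("parametric increment passes through its three anchors", {
  expect_equal(increment_per_1000iu(param_model, 0), 13, tolerance = 1e-9)
  expect_equal(increment_per_1000iu(param_model, 28), 4, tolerance = 1e-9)
  expect_equal(increment_per_1000iu(param_model, 140), 2, tolerance = 1e-9)
  # smooth, positive, non-increasing
  g <- increment_per_1000iu(param_model, seq(0, 200, by = 1))
  expect_true(all(g > 0))
  expect_true(all(diff(g) <= 0))
  # unsupported on the calibration backend
  expect_error(increment_per_1000iu(calib_model, 20), "parametric backend")
})

test_that("parametric achieved is monotone, above baseline, and dose-additive", {
  doses <- seq(0, 6000, by = 500)
  for (b in c(5, 14, 28, 60)) {
    a <- vapply(doses, function(d) achieved(param_model, b, d), numeric(1))
    expect_true(all(diff(a) > 0))         # strictly increasing in dose
    expect_true(all(a >= b))
  }
  # increasing in baseline at fixed dose
  a <- achieved(param_model, c(5, 14, 28, 60), 2000)
  expect_true(all(diff(a) > 0))
  # one 2000 IU/d pass equals two sequential 1000 IU/d passes
  one <- achieved(param_model, 14, 2000)
  two <- achieved(param_model, achieved(param_model, 14, 1000), 1000)
  expect_equal(one, two, tolerance = 1e-6)
  # diminishing returns: each added 1000 IU/d raises status by less
  steps <- vapply(0:3, function(k) {
    achieved(param_model, 14, (k + 1) * 1000) - achieved(param_model, 14, k * 1000)
  }, numeric(1))
  expect_true(all(diff(steps) < 0))
})

test_that("calibration grids round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(default_calibration_grid(), path)
  back <- read_calibration(path)
  expect_equal(back, default_calibration_grid())
  # the shipped fixture matches the in-code default
  shipped <- read_calibration(
    system.file("extdata", "achieved_25ohd_calibration.csv", package = "vdrct"))
  expect_equal(shipped, default_calibration_grid())
})
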