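# Shared objects built once per test run. The calibration grid's known
# non-monotone cell would warn on every construction, so helpers build the
# model with check = FALSE; the warning itself is tested explicitly.
default_curve <- dose_response_curve()
default_pop <- population_distribution()
calib_model <- status_response_model(check = FALSE)
param_model <- status_response_model("parametric")

# Textbook Woolf computation, written independently of the package path:
# operates on the four cells directly, used as the oracle for trial_stats.
woolf_oracle <- function(a, b, c, d, alpha = 0.05) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  list(or = or,
       lo = exp(log(or) - z * se),
       up = exp(log(or) + z * se),
       p = 2 * pnorm(-abs(log(or) / se)))
}

# Spreadsheet-style expected-case oracle: direct evaluation of
# r * N_i * OR_i / mean(OR over reference deciles).
cases_oracle <- function(conc, n_i, r = 0.0176,
                         ref = c(11, 14, 17, 20, 23, 26, 29, 33, 36, 40),
                         coef = 18.3, expo = -0.833) {
  r * n_i * (coef * conc^expo) / mean(coef * ref^expo)
}

# Reference grid of achieved concentrations (baseline rows x dose columns)
# as shipped; used to assert grid fidelity cell by cell.
reference_grid <- list(
  baselines = c(11, 14, 17, 20, 23, 26, 29, 33, 36, 40),
  doses = c(400, 1000, 2000, 4000),
  achieved = rbind(
    c(25, 29, 31, 45), c(18, 24, 33, 47), c(21, 28, 35, 49),
    c(24, 29, 37, 50), c(27, 32, 40, 51), c(29, 35, 42, 53),
    c(33, 37, 44, 55), c(36, 40, 47, 57), c(39, 43, 49, 59),
    c(43, 46, 52, 61))
)
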