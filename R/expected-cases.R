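#' Mean baseline odds ratio of a reference population
#'
#' The normalizing constant of the expected-case model: the arithmetic mean
#' of the dose-response odds ratios evaluated at every decile baseline of
#' the FULL reference population, regardless of which deciles a cohort
#' enrols. Dividing each decile's odds ratio by this mean calibrates the
#' model so that, with no supplementation, the whole population's expected
#' case total equals the background rate times total person-years.
#'
#' @param curve A [dose_response_curve()].
#' @param population A [population_distribution()].
#' @return The mean odds ratio (dimensionless).
#' @examples
#' normalizing_mean_or(dose_response_curve(), population_distribution())
#' @export
normalizing_mean_or <- function(curve, population) {
  stopifnot(inherits(curve, "dose_response_curve"),
            inherits(population, "population_distribution"))
  if (length(population$decile_baselines) == 0L) {
    stop("population has no deciles", call. = FALSE)
  }
  mean(odds_ratio_at(curve, population$decile_baselines))
}

#' Expected cancer cases per decile for a trial scenario
#'
#' For decile `i` with baseline `b_i`, achieved concentration `a_i` (from
#' the scenario's status model at the scenario dose, or the scenario's
#' explicit override) and per-arm person-years `N_i` (the arm total split
#' by the scenario weights), the expected counts are
#' `control_i = r * N_i * OR(b_i) / mean_OR` and
#' `treatment_i = r * N_i * OR(a_i) / mean_OR`, where `mean_OR` is
#' [normalizing_mean_or()] over the full reference population. Counts are
#' expected values and stay fractional; rounding to one decimal happens
#' only when rendering reports.
#'
#' @param scenario A [trial_scenario()].
#' @return An `expected_case_table`: a data frame with columns `baseline`,
#'   `achieved`, `control_person_years`, `treatment_person_years`,
#'   `control_cases`, `treatment_cases`, plus attributes `totals` (named
#'   vector, control/treatment case totals) and `scenario`.
#' @examples
#' sc <- trial_scenario(dose = 2000, selected_deciles = 6:10,
#'                      person_years_per_arm = 4000)
#' expected_cases(sc)
#' @export
expected_cases <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  b <- scenario$cohort_baselines
  a <- if (!is.null(scenario$achieved_override)) scenario$achieved_override
       else achieved(scenario$status_model, b, scenario$dose)
  m <- normalizing_mean_or(scenario$curve, scenario$population)
  or_b <- odds_ratio_at(scenario$curve, b)
  or_a <- odds_ratio_at(scenario$curve, a)
  n_ctrl <- scenario$person_years_per_arm * scenario$weights
  n_trt <- scenario$treatment_person_years * scenario$weights
  r <- scenario$incidence_rate
  tab <- data.frame(
    baseline = b,
    achieved = a,
    control_person_years = n_ctrl,
    treatment_person_years = n_trt,
    control_cases = r * n_ctrl * or_b / m,
    treatment_cases = r * n_trt * or_a / m
  )
  structure(tab,
            totals = c(control = sum(tab$control_cases),
                       treatment = sum(tab$treatment_cases)),
            normalizing_mean_or = m,
            scenario = scenario,
            class = c("expected_case_table", "data.frame"))
}

#' @export
print.expected_case_table <- function(x, digits = 1, ...) {
  cat("Expected cancer cases by baseline 25(OH)D decile\n")
  shown <- as.data.frame(x)
  shown$control_cases <- round(shown$control_cases, digits)
  shown$treatment_cases <- round(shown$treatment_cases, digits)
  print.data.frame(shown, row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("Totals: control %.*f, treatment %.*f cases\n",
              digits, tot[["control"]], digits, tot[["treatment"]]))
  invisible(x)
}

#' Write an expected-case table as CSV
#'
#' Unrounded numeric values, one row per decile plus a `total` row.
#'
#' @param x An [expected_cases()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expected_cases <- function(x, path) {
  stopifnot(inherits(x, "expected_case_table"))
  out <- as.data.frame(x)
  tot <- attr(x, "totals")
  out <- rbind(out, data.frame(
    baseline = NA, achieved = NA,
    control_person_years = sum(out$control_person_years),
    treatment_person_years = sum(out$treatment_person_years),
    control_cases = tot[["control"]], treatment_cases = tot[["treatment"]]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
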