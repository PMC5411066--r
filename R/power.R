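#' Odds ratio and confidence interval as a function of arm size
#'
#' Re-evaluates a scenario's expected-count odds-ratio statistics at each
#' person-years value in `n_grid` (both arms scaled together, preserving
#' the scenario's treatment/control ratio). Because expected counts scale
#' linearly with exposure, the odds ratio is constant across the grid and
#' only the confidence interval narrows as person-years grow.
#'
#' @param scenario A [trial_scenario()].
#' @param n_grid Strictly increasing positive person-years per (control)
#'   arm.
#' @return A `power_curve`: data frame with columns `person_years`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`.
#' @examples
#' sc <- trial_scenario(dose = 2000, selected_deciles = 1:5)
#' power_curve(sc, c(1000, 1500, 2000))
#' @export
power_curve <- function(scenario, n_grid) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (length(n_grid) == 0L || any(!is.finite(n_grid)) || any(n_grid <= 0)) {
    stop("`n_grid` must be non-empty, positive person-years", call. = FALSE)
  }
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be strictly increasing", call. = FALSE)
  }
  ratio <- scenario$treatment_person_years / scenario$person_years_per_arm
  rows <- lapply(n_grid, function(n) {
    sc <- scenario
    sc$person_years_per_arm <- n
    sc$treatment_person_years <- n * ratio
    est <- evaluate_scenario(sc)
    data.frame(person_years = n, odds_ratio = est$odds_ratio,
               ci_lower = est$ci_lower, ci_upper = est$ci_upper,
               p_value = est$p_value)
  })
  structure(do.call(rbind, rows),
            scenario = scenario,
            class = c("power_curve", "data.frame"))
}

#' @export
print.power_curve <- function(x, digits = 2, ...) {
  cat("Odds ratio and CI vs person-years per arm\n")
  shown <- as.data.frame(x)
  for (col in c("odds_ratio", "ci_lower", "ci_upper")) {
    shown[[col]] <- round(shown[[col]], digits)
  }
  shown$p_value <- signif(shown$p_value, 2)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Plot a power curve
#'
#' Base-graphics plot of the odds ratio with its confidence band against
#' person-years per arm, with the null line at 1.
#'
#' @param x A [power_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.power_curve <- function(x, ...) {
  graphics::plot(x$person_years, x$odds_ratio, type = "l",
                 ylim = range(1, x$ci_lower, x$ci_upper),
                 xlab = "Person-years per arm", ylab = "Odds ratio", ...)
  graphics::lines(x$person_years, x$ci_lower, lty = 2)
  graphics::lines(x$person_years, x$ci_upper, lty = 2)
  graphics::abline(h = 1, col = "grey50")
  invisible(x)
}

#' Person-years per arm required for significance
#'
#' Scans person-years per arm in multiples of `step` and returns the
#' smallest value at which the Woolf upper `1 - alpha` confidence bound on
#' the expected-count odds ratio falls below 1. At a fixed protective
#' effect the upper bound decreases monotonically in person-years, so the
#' crossing is unique; the scan is exact (no curve is fitted through the
#' CI points).
#'
#' @param scenario A [trial_scenario()] whose expected-count odds ratio is
#'   below 1 (a protective effect); otherwise an error of class
#'   `vdrct_no_solution` is thrown.
#' @param step Scan step in person-years (> 0), default 100.
#' @param n_max Upper search bound; if the bound is not crossed by `n_max`
#'   the result carries `reached = FALSE` and an `NA` size.
#' @return A `required_n` object: list with `person_years_per_arm`,
#'   `reached`, `estimate` (the effect at the solution), `step`, `n_max`.
#' @examples
#' sc <- trial_scenario(dose = 2000, cohort_baselines = 26,
#'                      achieved_override = 42)
#' required_n(sc)
#' @export
required_n <- function(scenario, step = 100, n_max = 1e6) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < step) {
    stop("`n_max` must be at least `step`", call. = FALSE)
  }
  base <- evaluate_scenario(scenario)
  if (base$odds_ratio >= 1) {
    stop(structure(class = c("vdrct_no_solution", "error", "condition"),
                   list(message = sprintf(
                     "no solution: the expected-count odds ratio is %.4g >= 1, so the upper confidence bound can never fall below 1",
                     base$odds_ratio), call = NULL)))
  }
  ratio <- scenario$treatment_person_years / scenario$person_years_per_arm
  upper_at <- function(n) {
    sc <- scenario
    sc$person_years_per_arm <- n
    sc$treatment_person_years <- n * ratio
    evaluate_scenario(sc)
  }
  n <- step
  while (n <= n_max) {
    est <- upper_at(n)
    if (est$ci_upper < 1) {
      return(structure(list(person_years_per_arm = n, reached = TRUE,
                            estimate = est, step = step, n_max = n_max),
                       class = "required_n"))
    }
    n <- n + step
  }
  structure(list(person_years_per_arm = NA_real_, reached = FALSE,
                 estimate = NULL, step = step, n_max = n_max),
            class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "Required person-years per arm: %g (step %g)\n  effect there: %s\n",
      x$person_years_per_arm, x$step, format(x$estimate)))
  } else {
    cat(sprintf(
      "Upper confidence bound did not fall below 1 within %g person-years per arm\n",
      x$n_max))
  }
  invisible(x)
}

#' Write a power curve as CSV
#'
#' Columns `person_years`, `odds_ratio`, `ci_lower`, `ci_upper`,
#' `p_value`, unrounded.
#'
#' @param x A [power_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_power_curve <- function(x, path) {
  stopifnot(inherits(x, "power_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
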