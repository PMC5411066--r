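#' Two-by-two table of cases and person-years per arm
#'
#' Cell counts may be fractional: the design model feeds expected (mean)
#' case counts into the same asymptotic formulas used for observed integer
#' counts. Non-cases (person-years minus cases) must be strictly positive
#' in each arm.
#'
#' @param treatment_cases,control_cases Case counts (>= 0, possibly
#'   fractional).
#' @param treatment_person_years,control_person_years Person-years at risk
#'   per arm (> cases).
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(11.7, 1000, 22.5, 1000)
#' @export
two_by_two <- function(treatment_cases, treatment_person_years,
                       control_cases, control_person_years) {
  vals <- c(treatment_cases, treatment_person_years,
            control_cases, control_person_years)
  if (length(vals) != 4L || any(!is.finite(vals))) {
    stop("all four cells must be single finite numbers", call. = FALSE)
  }
  if (treatment_cases < 0 || control_cases < 0) {
    stop("case counts must be non-negative", call. = FALSE)
  }
  if (treatment_person_years <= treatment_cases ||
      control_person_years <= control_cases) {
    stop("person-years must exceed cases in each arm (non-cases must be positive)",
         call. = FALSE)
  }
  structure(list(treatment_cases = treatment_cases,
                 treatment_person_years = treatment_person_years,
                 control_cases = control_cases,
                 control_person_years = control_person_years),
            class = "two_by_two")
}

#' Odds ratio, Woolf confidence interval, p-value and relative risk
#'
#' With `a` treatment cases, `b = N_t - a` treatment non-cases, `c` control
#' cases and `d = N_c - c` control non-cases:
#' `OR = (a/b)/(c/d)`; the Woolf interval is
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the exact
#' `1 - alpha/2` normal quantile; the two-sided p-value comes from the
#' standard normal on `ln OR / SE`; and `RR = (a/N_t)/(c/N_c)`. No
#' continuity correction and no exact test: all formulas are evaluated
#' as-is on (possibly fractional) expected counts, so any zero cell is an
#' error rather than a corrected value.
#'
#' The printed effect estimates of the trials this model is compared with
#' numerically match the odds ratio even where labelled a relative risk;
#' both quantities are therefore returned explicitly.
#'
#' @param x A [two_by_two()] table or an [expected_cases()] table (whose
#'   arm totals form the 2x2).
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param ... Passed between methods.
#' @return An `effect_estimate`: list with `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `relative_risk`, `alpha`, `se_log_or` and the
#'   input `table`.
#' @examples
#' odds_ratio_ci(two_by_two(11.7, 1000, 22.5, 1000))
#' @export
odds_ratio_ci <- function(x, alpha = 0.05, ...) UseMethod("odds_ratio_ci")

#' @rdname odds_ratio_ci
#' @export
odds_ratio_ci.two_by_two <- function(x, alpha = 0.05, ...) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  a <- x$treatment_cases
  b <- x$treatment_person_years - x$treatment_cases
  c_ <- x$control_cases
  d <- x$control_person_years - x$control_cases
  if (a == 0 || c_ == 0) {
    stop("a 2x2 cell is zero; continuity corrections are out of scope for ",
         "expected-count inputs, so the odds ratio is undefined here",
         call. = FALSE)
  }
  or <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  est <- list(
    odds_ratio = or,
    ci_lower = exp(log(or) - z * se),
    ci_upper = exp(log(or) + z * se),
    p_value = 2 * stats::pnorm(-abs(log(or) / se)),
    relative_risk = (a / x$treatment_person_years) /
      (c_ / x$control_person_years),
    alpha = alpha,
    se_log_or = se,
    table = x
  )
  class(est) <- "effect_estimate"
  est
}

#' @rdname odds_ratio_ci
#' @export
odds_ratio_ci.expected_case_table <- function(x, alpha = 0.05, ...) {
  tot <- attr(x, "totals")
  tab <- two_by_two(tot[["treatment"]], sum(x$treatment_person_years),
                    tot[["control"]], sum(x$control_person_years))
  odds_ratio_ci(tab, alpha = alpha)
}

#' Evaluate a scenario end-to-end to a single effect estimate
#'
#' Convenience composition: expected cases for the scenario, then the
#' Woolf odds-ratio statistics on the arm totals at the scenario's alpha.
#'
#' @param scenario A [trial_scenario()].
#' @return An `effect_estimate`.
#' @export
evaluate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  odds_ratio_ci(expected_cases(scenario), alpha = scenario$alpha)
}

#' Render an effect estimate in the conventional "OR (lo-hi)" style
#'
#' @param x An `effect_estimate`.
#' @param digits Decimals for OR and CI bounds (default 2).
#' @param p Include `, P = ...`.
#' @param ... Unused.
#' @return A character string such as `"0.51 (0.25–1.05)"`.
#' @export
format.effect_estimate <- function(x, digits = 2, p = FALSE, ...) {
  s <- sprintf("%.*f (%.*f–%.*f)", digits, x$odds_ratio,
               digits, x$ci_lower, digits, x$ci_upper)
  if (p) s <- sprintf("%.*f (%.*f–%.*f, P = %.2f)", digits, x$odds_ratio,
                      digits, x$ci_lower, digits, x$ci_upper, x$p_value)
  s
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  pct <- 100 * (1 - x$alpha)
  cat(sprintf("Odds ratio: %s  [%g%% CI, Woolf]\n",
              format(x, digits = digits), pct))
  cat(sprintf("Relative risk: %.*f;  two-sided P = %.4g\n",
              digits, x$relative_risk, x$p_value))
  invisible(x)
}
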