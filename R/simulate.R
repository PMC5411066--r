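#' Monte Carlo individual-level trial simulation
#'
#' Stochastic counterpart of the expected-count model, used to validate it
#' and to estimate empirical power. Person-years are allocated across the
#' cohort's deciles by the scenario weights (deterministically — only case
#' events are random, isolating the variance the expected-count model
#' ignores). Each control-arm person-year becomes a case with probability
#' `r * OR(baseline_i) / mean_OR` and each treatment-arm person-year with
#' `r * OR(achieved_i) / mean_OR`; per-decile counts are binomial draws.
#' A replicate is significant when the Woolf upper confidence bound on its
#' realised 2x2 falls below 1; replicates with a zero case cell are counted
#' as non-significant rather than dropped (relevant only at tiny arm
#' sizes).
#'
#' @param scenario A [trial_scenario()].
#' @param replicates Number of simulated trials (>= 1).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#'   The caller's random-number state is saved and restored.
#' @return A `trial_simulation`: list with `replicates`, `draws` (data
#'   frame of per-replicate `control_cases`, `treatment_cases`,
#'   `significant`), `empirical_power`, `mean_cases` (named control /
#'   treatment means), `expected` (the analytic [expected_cases()]
#'   totals), and `seed`.
#' @examples
#' sc <- trial_scenario(dose = 2000, selected_deciles = 6:10,
#'                      person_years_per_arm = 4000)
#' simulate_trial(sc, replicates = 200, seed = 1)
#' @export
simulate_trial <- function(scenario, replicates, seed) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1) {
    stop("`replicates` must be at least 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be a single integer for reproducibility", call. = FALSE)
  }

  b <- scenario$cohort_baselines
  a <- if (!is.null(scenario$achieved_override)) scenario$achieved_override
       else achieved(scenario$status_model, b, scenario$dose)
  m <- normalizing_mean_or(scenario$curve, scenario$population)
  r <- scenario$incidence_rate
  p_ctrl <- r * odds_ratio_at(scenario$curve, b) / m
  p_trt <- r * odds_ratio_at(scenario$curve, a) / m
  if (any(p_ctrl >= 1) || any(p_trt >= 1)) {
    bad <- which(p_ctrl >= 1 | p_trt >= 1)[1L]
    stop(sprintf(
      "per person-year case probability reaches 1 in cohort stratum %d (baseline %g ng/mL); reduce the incidence rate or odds ratio",
      bad, b[bad]), call. = FALSE)
  }
  n_ctrl <- round(scenario$person_years_per_arm * scenario$weights)
  n_trt <- round(scenario$treatment_person_years * scenario$weights)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  k <- length(b)
  ctrl_draws <- matrix(stats::rbinom(replicates * k, size = rep(n_ctrl, each = replicates),
                                     prob = rep(p_ctrl, each = replicates)),
                       nrow = replicates)
  trt_draws <- matrix(stats::rbinom(replicates * k, size = rep(n_trt, each = replicates),
                                    prob = rep(p_trt, each = replicates)),
                      nrow = replicates)
  control_cases <- rowSums(ctrl_draws)
  treatment_cases <- rowSums(trt_draws)

  N_c <- sum(n_ctrl)
  N_t <- sum(n_trt)
  significant <- vapply(seq_len(replicates), function(i) {
    ac <- treatment_cases[i]; cc <- control_cases[i]
    if (ac == 0 || cc == 0 || ac >= N_t || cc >= N_c) return(FALSE)
    est <- odds_ratio_ci(two_by_two(ac, N_t, cc, N_c), alpha = scenario$alpha)
    est$ci_upper < 1
  }, logical(1L))

  exp_tab <- expected_cases(scenario)
  structure(list(
    replicates = replicates,
    draws = data.frame(control_cases = control_cases,
                       treatment_cases = treatment_cases,
                       significant = significant),
    empirical_power = mean(significant),
    mean_cases = c(control = mean(control_cases),
                   treatment = mean(treatment_cases)),
    expected = attr(exp_tab, "totals"),
    seed = as.integer(seed)
  ), class = "trial_simulation")
}

#' @export
print.trial_simulation <- function(x, ...) {
  cat(sprintf("Monte Carlo trial simulation: %d replicates (seed %d)\n",
              x$replicates, x$seed))
  cat(sprintf("  mean cases: control %.2f (expected %.2f), treatment %.2f (expected %.2f)\n",
              x$mean_cases[["control"]], x$expected[["control"]],
              x$mean_cases[["treatment"]], x$expected[["treatment"]]))
  cat(sprintf("  empirical power (upper CI < 1): %.3f\n", x$empirical_power))
  invisible(x)
}

#' @export
summary.trial_simulation <- function(object, ...) {
  d <- object$draws
  out <- list(
    replicates = object$replicates,
    empirical_power = object$empirical_power,
    power_se = sqrt(object$empirical_power * (1 - object$empirical_power) /
                      object$replicates),
    control = c(mean = mean(d$control_cases), sd = stats::sd(d$control_cases),
                expected = object$expected[["control"]]),
    treatment = c(mean = mean(d$treatment_cases), sd = stats::sd(d$treatment_cases),
                  expected = object$expected[["treatment"]])
  )
  class(out) <- "summary.trial_simulation"
  out
}

#' @export
print.summary.trial_simulation <- function(x, ...) {
  cat(sprintf("Replicates: %d; empirical power %.3f (SE %.3f)\n",
              x$replicates, x$empirical_power, x$power_se))
  cat(sprintf("Control cases: mean %.2f, sd %.2f, analytic expectation %.2f\n",
              x$control[["mean"]], x$control[["sd"]], x$control[["expected"]]))
  cat(sprintf("Treatment cases: mean %.2f, sd %.2f, analytic expectation %.2f\n",
              x$treatment[["mean"]], x$treatment[["sd"]], x$treatment[["expected"]]))
  invisible(x)
}

#' Write per-replicate simulation draws as CSV
#'
#' @param x A [simulate_trial()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(x, path) {
  stopifnot(inherits(x, "trial_simulation"))
  utils::write.csv(x$draws, path, row.names = FALSE)
  invisible(path)
}
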