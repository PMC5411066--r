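#' Reference population distribution of baseline 25(OH)D
#'
#' A population's baseline vitamin D status represented by the midpoints of
#' its ten deciles of serum 25(OH)D. The default is the Canadian ages 50-79
#' distribution used throughout the package.
#'
#' @param decile_baselines Strictly increasing 25(OH)D concentrations
#'   (ng/mL), all at least 1.
#' @param label Free-text description.
#' @return An object of class `population_distribution`.
#' @export
population_distribution <- function(
    decile_baselines = c(11, 14, 17, 20, 23, 26, 29, 33, 36, 40),
    label = "Canadian ages 50-79") {
  b <- as.numeric(decile_baselines)
  if (length(b) == 0L) {
    stop("`decile_baselines` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(b)) || any(b < 1)) {
    stop("all decile baselines must be finite and >= 1 ng/mL", call. = FALSE)
  }
  if (is.unsorted(b, strictly = TRUE)) {
    stop("`decile_baselines` must be strictly increasing", call. = FALSE)
  }
  structure(list(decile_baselines = b, label = as.character(label)[1L]),
            class = "population_distribution")
}

#' @export
print.population_distribution <- function(x, ...) {
  cat(sprintf("Population distribution (%s): %d decile baselines [ng/mL]\n  %s\n",
              x$label, length(x$decile_baselines),
              paste(x$decile_baselines, collapse = ", ")))
  invisible(x)
}

#' Trial design scenario
#'
#' Bundles everything needed to evaluate a two-arm vitamin D RCT design:
#' the reference population, the cohort actually enrolled (a subset of the
#' population's deciles, or explicit baseline concentrations), the daily
#' dose, the background cancer incidence rate, person-years per arm, the
#' dose-response curve, the status-response model and the significance
#' level.
#'
#' Person-years are the exposure primitive (one participant followed for
#' one year contributes one person-year); a fixed enrolment over several
#' years is expressed as participants x years. Allocation across the
#' cohort's deciles is equal by default and can be overridden with
#' `weights`. Expected-case normalization always uses the full reference
#' population's mean baseline odds ratio, even when the enrolled cohort is
#' a subset or a single concentration.
#'
#' @param dose Daily vitamin D3 dose, IU/d (>= 0).
#' @param population Reference [population_distribution()].
#' @param selected_deciles Indices into the population's deciles that the
#'   cohort enrols (default all).
#' @param cohort_baselines Optional explicit cohort baseline concentrations
#'   (ng/mL) overriding `selected_deciles` (e.g. a single-concentration
#'   cohort).
#' @param achieved_override Optional achieved concentrations (ng/mL), one
#'   per cohort baseline, bypassing the status model.
#' @param incidence_rate Background cancer incidence, cases per person-year,
#'   in (0, 1). Default 0.0176 (all-cancer, ages 65-69, 1760 per
#'   100,000/yr).
#' @param person_years_per_arm Control-arm person-years (> 0).
#' @param treatment_person_years Treatment-arm person-years; defaults to
#'   the control arm's.
#' @param weights Per-decile allocation weights (normalized internally);
#'   default equal.
#' @param curve [dose_response_curve()].
#' @param status_model [status_response_model()].
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return An object of class `trial_scenario`.
#' @examples
#' sc <- trial_scenario(dose = 2000, selected_deciles = 1:5,
#'                      person_years_per_arm = 1000)
#' expected_cases(sc)
#' @export
trial_scenario <- function(dose,
                           population = population_distribution(),
                           selected_deciles = seq_along(population$decile_baselines),
                           cohort_baselines = NULL,
                           achieved_override = NULL,
                           incidence_rate = 0.0176,
                           person_years_per_arm = 4000,
                           treatment_person_years = person_years_per_arm,
                           weights = NULL,
                           curve = dose_response_curve(),
                           status_model = status_response_model(check = FALSE),
                           alpha = 0.05) {
  stopifnot(inherits(population, "population_distribution"),
            inherits(curve, "dose_response_curve"),
            inherits(status_model, "status_response_model"))
  if (length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("`dose` must be a single non-negative IU/d value", call. = FALSE)
  }
  if (!is.numeric(incidence_rate) || length(incidence_rate) != 1L ||
      incidence_rate <= 0 || incidence_rate >= 1) {
    stop("`incidence_rate` must lie strictly between 0 and 1 cases per person-year",
         call. = FALSE)
  }
  if (!is.numeric(person_years_per_arm) || person_years_per_arm <= 0 ||
      !is.numeric(treatment_person_years) || treatment_person_years <= 0) {
    stop("person-years per arm must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(cohort_baselines)) {
    selected_deciles <- as.integer(selected_deciles)
    if (length(selected_deciles) == 0L) {
      stop("`selected_deciles` must be a non-empty subset", call. = FALSE)
    }
    if (any(is.na(selected_deciles)) ||
        any(selected_deciles < 1L) ||
        any(selected_deciles > length(population$decile_baselines)) ||
        anyDuplicated(selected_deciles)) {
      stop("`selected_deciles` must be distinct indices into the population deciles",
           call. = FALSE)
    }
    cohort <- population$decile_baselines[selected_deciles]
  } else {
    cohort <- as.numeric(cohort_baselines)
    if (length(cohort) == 0L || any(!is.finite(cohort)) || any(cohort < 1)) {
      stop("`cohort_baselines` must be finite concentrations >= 1 ng/mL",
           call. = FALSE)
    }
    selected_deciles <- NULL
  }
  if (!is.null(achieved_override)) {
    achieved_override <- as.numeric(achieved_override)
    if (length(achieved_override) != length(cohort)) {
      stop("`achieved_override` must supply one value per cohort baseline",
           call. = FALSE)
    }
    if (any(achieved_override < cohort)) {
      stop("achieved concentrations cannot lie below their baselines",
           call. = FALSE)
    }
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(cohort), length(cohort))
  } else {
    if (length(weights) != length(cohort) || any(weights <= 0)) {
      stop("`weights` must be positive, one per cohort baseline", call. = FALSE)
    }
    weights <- weights / sum(weights)
  }
  structure(
    list(population = population, selected_deciles = selected_deciles,
         cohort_baselines = cohort, achieved_override = achieved_override,
         dose = dose, incidence_rate = incidence_rate,
         person_years_per_arm = person_years_per_arm,
         treatment_person_years = treatment_person_years,
         weights = weights, curve = curve, status_model = status_model,
         alpha = alpha),
    class = "trial_scenario"
  )
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Two-arm trial design scenario\n")
  cat(sprintf("  dose: %g IU/d; incidence rate: %g /person-year; alpha: %g\n",
              x$dose, x$incidence_rate, x$alpha))
  cat(sprintf("  person-years per arm: control %g, treatment %g\n",
              x$person_years_per_arm, x$treatment_person_years))
  cat(sprintf("  cohort baselines [ng/mL]: %s\n",
              paste(x$cohort_baselines, collapse = ", ")))
  cat(sprintf("  reference population: %s (%d deciles)\n",
              x$population$label, length(x$population$decile_baselines)))
  if (!is.null(x$achieved_override)) {
    cat(sprintf("  achieved override [ng/mL]: %s\n",
                paste(x$achieved_override, collapse = ", ")))
  }
  invisible(x)
}

#' Load or save a trial scenario as a YAML config
#'
#' Flat-key YAML; any omitted key takes its documented default, and the
#' defaults applied are reported with a message at load time so a rendered
#' table is auditable. Recognised keys: `dose`, `incidence_rate`, `alpha`,
#' `person_years_per_arm`, `treatment_person_years`, `population`
#' (list of decile baselines), `population_label`, `selected_deciles`,
#' `cohort_baselines`, `achieved_override`, `weights`, `curve`
#' (`coefficient`, `exponent`, `min_concentration`), `status_backend`.
#'
#' @param path YAML file path.
#' @param quiet Suppress the defaults-applied message.
#' @return `load_scenario()` returns a [trial_scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
load_scenario <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("scenario config must be a YAML mapping", call. = FALSE)
  known <- c("dose", "incidence_rate", "alpha", "person_years_per_arm",
             "treatment_person_years", "population", "population_label",
             "selected_deciles", "cohort_baselines", "achieved_override",
             "weights", "curve", "status_backend")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unrecognised scenario keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$dose)) {
    stop("scenario config is missing required key: dose", call. = FALSE)
  }
  pop <- if (is.null(cfg$population)) population_distribution() else {
    population_distribution(unlist(cfg$population),
                            label = cfg$population_label %||% "config population")
  }
  curve <- if (is.null(cfg$curve)) dose_response_curve() else {
    dose_response_curve(
      coefficient = cfg$curve$coefficient %||% 18.3,
      exponent = cfg$curve$exponent %||% -0.833,
      min_concentration = cfg$curve$min_concentration %||% 1)
  }
  backend <- cfg$status_backend %||% "calibration"
  args <- list(
    dose = cfg$dose, population = pop, curve = curve,
    status_model = status_response_model(backend = backend, check = FALSE))
  opt <- c("incidence_rate", "alpha", "person_years_per_arm",
           "treatment_person_years", "selected_deciles", "cohort_baselines",
           "achieved_override", "weights")
  for (key in opt) {
    if (is.null(cfg[[key]])) next
    if (length(cfg[[key]]) == 0L) {  # explicit empty list, e.g. deciles: []
      args[key] <- list(numeric(0))
      next
    }
    val <- unlist(cfg[[key]])
    # YAML 1.1 reads exponent forms without a decimal point (1760e-5) as
    # strings; coerce anything that parses cleanly as numbers
    if (is.character(val) && !anyNA(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    args[[key]] <- val
  }
  defaulted <- setdiff(c(opt, "population", "curve", "status_backend"),
                       names(cfg))
  if (!quiet && length(defaulted)) {
    message("scenario defaults applied for: ", paste(defaulted, collapse = ", "))
  }
  do.call(trial_scenario, args)
}

#' @param scenario A [trial_scenario()].
#' @rdname load_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "trial_scenario"))
  cfg <- list(
    dose = scenario$dose,
    incidence_rate = scenario$incidence_rate,
    alpha = scenario$alpha,
    person_years_per_arm = scenario$person_years_per_arm,
    treatment_person_years = scenario$treatment_person_years,
    population = scenario$population$decile_baselines,
    population_label = scenario$population$label,
    weights = scenario$weights,
    curve = list(coefficient = scenario$curve$coefficient,
                 exponent = scenario$curve$exponent,
                 min_concentration = scenario$curve$min_concentration),
    status_backend = scenario$status_model$backend
  )
  if (!is.null(scenario$selected_deciles)) {
    cfg$selected_deciles <- scenario$selected_deciles
  } else {
    cfg$cohort_baselines <- scenario$cohort_baselines
  }
  if (!is.null(scenario$achieved_override)) {
    cfg$achieved_override <- scenario$achieved_override
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
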