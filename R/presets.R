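#' Built-in scenario presets
#'
#' Named trial-design scenarios used by the package's worked reports:
#'
#' * `"table2"` — full ten-decile reference population, 4000 person-years
#'   per arm (400 per decile); the expected-case table is tabulated for
#'   several doses.
#' * `"table3"` — lowest five deciles at 2000 IU/d (deficient-cohort
#'   design).
#' * `"table5"` — highest five deciles at 2000 IU/d, 4000 person-years per
#'   arm (replete-cohort design, comparable to the 2017 Nebraska trial).
#' * `"table4_totals"` — five deciles centred at 29 ng/mL at 1000 IU/d
#'   with unequal arms (control 266, treatment 403 participants followed 3
#'   years), matching the 2007 Nebraska trial's exposure; only its 2x2
#'   totals are modelled (see [rct_comparison_counts()] for the published
#'   counts).
#' * `"fig3"` — single-concentration cohort, baseline 14 ng/mL, achieved
#'   34 ng/mL at 2000 IU/d.
#' * `"fig4"` — single-concentration cohort, baseline 26 ng/mL, achieved
#'   42 ng/mL at 2000 IU/d.
#'
#' All presets use the default curve, rate 0.0176 cases/person-year, and
#' normalization by the full reference population.
#'
#' @param name Preset name.
#' @return A [trial_scenario()].
#' @examples
#' evaluate_scenario(scenario_preset("table5"))
#' @export
scenario_preset <- function(name) {
  presets <- c("table2", "table3", "table4_totals", "table5", "fig3", "fig4")
  if (length(name) != 1L || !name %in% presets) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  sm <- status_response_model(check = FALSE)
  switch(name,
    table2 = trial_scenario(dose = 2000, person_years_per_arm = 4000,
                            status_model = sm),
    table3 = trial_scenario(dose = 2000, selected_deciles = 1:5,
                            person_years_per_arm = 1000, status_model = sm),
    table4_totals = trial_scenario(dose = 1000, selected_deciles = 5:9,
                                   person_years_per_arm = 266 * 3,
                                   treatment_person_years = 403 * 3,
                                   status_model = sm),
    table5 = trial_scenario(dose = 2000, selected_deciles = 6:10,
                            person_years_per_arm = 4000, status_model = sm),
    fig3 = trial_scenario(dose = 2000, cohort_baselines = 14,
                          achieved_override = 34, person_years_per_arm = 1000,
                          status_model = sm),
    fig4 = trial_scenario(dose = 2000, cohort_baselines = 26,
                          achieved_override = 42, person_years_per_arm = 4000,
                          status_model = sm)
  )
}

#' Published 2x2 counts from compared vitamin D RCTs
#'
#' Case counts and person-years per arm as published by the trials the
#' model is compared against. Person-years are exact participant-year
#' products (e.g. 266 participants x 3 years = 798), not the rounded
#' figures sometimes displayed.
#'
#' * `nebraska2007_3yr` / `nebraska2007_4yr` — model-expected totals for
#'   the 2007 Nebraska (vitamin D + calcium vs placebo) comparison at 3
#'   and 4 years of the unequal-arm design.
#' * `whi_no_prior_supp` — Women's Health Initiative participants without
#'   prior vitamin D/calcium supplementation.
#' * `nebraska2017` — the 2017 Nebraska trial (2000 IU/d + calcium),
#'   4128 person-years per arm.
#'
#' @return A data frame with columns `label`, `treatment_cases`,
#'   `treatment_person_years`, `control_cases`, `control_person_years`.
#' @export
rct_comparison_counts <- function() {
  data.frame(
    label = c("nebraska2007_3yr", "nebraska2007_4yr",
              "whi_no_prior_supp", "nebraska2017"),
    treatment_cases = c(11.9, 15.9, 633, 45),
    treatment_person_years = c(403 * 3, 403 * 4, 7891, 4128),
    control_cases = c(11.1, 14.8, 715, 64),
    control_person_years = c(266 * 3, 266 * 4, 7755, 4128)
  )
}
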