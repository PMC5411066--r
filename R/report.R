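fmt1 <- function(x) sprintf("%.1f", x)

or_string <- function(est, p = FALSE) format(est, digits = 2, p = p)

report_table <- function(title, rows, data) {
  structure(list(title = title, columns = names(rows), rows = rows,
                 data = data),
            class = "report_table")
}

#' Render a built-in report end-to-end
#'
#' Runs the named preset scenario through the full pipeline (status model,
#' expected cases, Woolf statistics, and for the figure presets the
#' required-N solver) and renders the result in the conventional layout:
#' case counts to one decimal, odds ratios and confidence bounds to two,
#' effect columns as `"OR (lo–hi)"` strings. Rendering is a pure function
#' of the computed numbers; the unrounded values are returned alongside in
#' `$data`.
#'
#' Available names: `table2` (expected cases by decile and dose), `table3`
#' (deficient-cohort design at increasing person-years), `table4_totals`
#' (published-count comparison with the 2007 Nebraska trial), `table5`
#' (replete-cohort design plus the 2017 Nebraska comparison), `fig3` and
#' `fig4` (odds ratio and CI vs person-years with the required arm size).
#'
#' @param name Preset name (see above).
#' @return A `report_table`: list with `title`, `columns`, `rows` (a
#'   character data frame as rendered) and `data` (the unrounded numeric
#'   results; for the figure presets a list with the power curve and the
#'   [required_n()] result).
#' @examples
#' render_paper_table("table5")
#' @export
render_paper_table <- function(name) {
  presets <- c("table2", "table3", "table4_totals", "table5", "fig3", "fig4")
  if (length(name) != 1L || !name %in% presets) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  switch(name,
         table2 = render_table2(),
         table3 = render_table3(),
         table4_totals = render_table4_totals(),
         table5 = render_table5(),
         fig3 = render_power_figure("fig3"),
         fig4 = render_power_figure("fig4"))
}

render_table2 <- function() {
  doses <- c(0, 400, 1000, 2000, 4000)
  base <- scenario_preset("table2")
  cols <- lapply(doses, function(d) {
    sc <- base
    sc$dose <- d
    expected_cases(sc)$treatment_cases
  })
  data <- data.frame(decile = seq_along(base$cohort_baselines),
                     baseline = base$cohort_baselines)
  labels <- c("baseline", paste0(doses[-1], " IU/d"))
  for (i in seq_along(doses)) data[[paste0("cases_", labels[i])]] <- cols[[i]]
  rows <- data.frame(Decile = c(as.character(data$decile), "Sum"),
                     `Baseline 25(OH)D (ng/mL)` = c(fmt1(data$baseline), ""),
                     check.names = FALSE)
  for (i in seq_along(doses)) {
    rows[[paste0("Cases, ", labels[i])]] <-
      c(fmt1(cols[[i]]), fmt1(sum(cols[[i]])))
  }
  report_table(
    "Expected cancer cases by baseline 25(OH)D decile and daily dose (400 person-years per decile per arm)",
    rows, data)
}

render_table3 <- function() {
  sc <- scenario_preset("table3")
  per <- expected_cases(sc)  # at 1000 person-years: 200 per decile
  per400 <- expected_cases({ s <- sc; s$person_years_per_arm <- 2000
                             s$treatment_person_years <- 2000; s })
  pc <- power_curve(sc, c(1000, 1500, 2000))
  rows <- data.frame(
    Decile = c(as.character(1:5), "Sum", "", ""),
    N = c(rep("400", 5), "1000", "1500", "2000"),
    `Baseline 25(OH)D (ng/mL)` = c(fmt1(sc$cohort_baselines), "", "", ""),
    `Cases, control arm` = c(fmt1(per400$control_cases),
                             fmt1(pc$person_years / 1000 *
                                    sum(per$control_cases))),
    `Cases, treatment arm` = c(fmt1(per400$treatment_cases),
                               fmt1(pc$person_years / 1000 *
                                      sum(per$treatment_cases))),
    `OR (95% CI)` = c(rep("", 5), vapply(seq_len(nrow(pc)), function(i) {
      sprintf("%.2f (%.2f–%.2f)", pc$odds_ratio[i], pc$ci_lower[i],
              pc$ci_upper[i])
    }, character(1L))),
    check.names = FALSE)
  report_table(
    "Deficient-cohort design: lowest five deciles at 2000 IU/d",
    rows, list(per_decile = per400, curve = pc))
}

render_table4_totals <- function() {
  counts <- rct_comparison_counts()
  sub <- counts[counts$label %in% c("nebraska2007_3yr", "nebraska2007_4yr"), ]
  ests <- lapply(seq_len(nrow(sub)), function(i) {
    odds_ratio_ci(two_by_two(sub$treatment_cases[i],
                             sub$treatment_person_years[i],
                             sub$control_cases[i],
                             sub$control_person_years[i]))
  })
  rows <- data.frame(
    Period = c("Total, 3 years", "Total, 4 years"),
    `N control` = as.character(sub$control_person_years),
    `N treatment` = as.character(sub$treatment_person_years),
    `Cases, control arm` = fmt1(sub$control_cases),
    `Cases, treatment arm` = fmt1(sub$treatment_cases),
    `OR (95% CI, P)` = vapply(ests, or_string, character(1L), p = TRUE),
    check.names = FALSE)
  report_table(
    "Unequal-arm comparison with the 2007 Nebraska trial (published 2x2 totals, 1000 IU/d cohort centred at 29 ng/mL)",
    rows, ests)
}

render_table5 <- function() {
  sc <- scenario_preset("table5")
  per400 <- expected_cases({ s <- sc; s$person_years_per_arm <- 2000
                             s$treatment_person_years <- 2000; s })
  pc <- power_curve(sc, c(2000, 4000, 10000))
  lappe <- rct_comparison_counts()
  lappe <- lappe[lappe$label == "nebraska2017", ]
  lappe_est <- odds_ratio_ci(two_by_two(
    lappe$treatment_cases, lappe$treatment_person_years,
    lappe$control_cases, lappe$control_person_years))
  per_tab <- expected_cases(sc)
  rows <- data.frame(
    Decile = c(as.character(6:10), "Sum", "", "", "Reported (2017 trial)"),
    N = c(rep("400", 5), "2000", "4000", "10000",
          as.character(lappe$treatment_person_years)),
    `Baseline 25(OH)D (ng/mL)` = c(fmt1(sc$cohort_baselines), "", "", "", ""),
    `Cases, treatment arm` = c(fmt1(per400$treatment_cases),
                               fmt1(pc$person_years / 2000 *
                                      sum(per400$treatment_cases)),
                               as.character(lappe$treatment_cases)),
    `Cases, control arm` = c(fmt1(per400$control_cases),
                             fmt1(pc$person_years / 2000 *
                                    sum(per400$control_cases)),
                             as.character(lappe$control_cases)),
    `OR (95% CI)` = c(rep("", 5), vapply(seq_len(nrow(pc)), function(i) {
      sprintf("%.2f (%.2f–%.2f)", pc$odds_ratio[i], pc$ci_lower[i],
              pc$ci_upper[i])
    }, character(1L)), or_string(lappe_est)),
    check.names = FALSE)
  report_table(
    "Replete-cohort design: highest five deciles at 2000 IU/d, with the 2017 Nebraska trial's published counts",
    rows, list(per_decile = per_tab, curve = pc, reported = lappe_est))
}

render_power_figure <- function(which) {
  sc <- scenario_preset(which)
  req <- required_n(sc, step = 100)
  n_hi <- max(req$person_years_per_arm * 2, 1000)
  grid <- seq(100, n_hi, by = 100)
  pc <- power_curve(sc, grid)
  rows <- data.frame(
    `Person-years per arm` = as.character(pc$person_years),
    `OR (95% CI)` = sprintf("%.2f (%.2f–%.2f)", pc$odds_ratio,
                            pc$ci_lower, pc$ci_upper),
    check.names = FALSE)
  title <- sprintf(
    "Odds ratio and 95%% CI vs person-years per arm (baseline %g, achieved %g ng/mL); required per-arm size: %g",
    sc$cohort_baselines, sc$achieved_override, req$person_years_per_arm)
  report_table(title, rows, list(curve = pc, required = req))
}

#' @export
print.report_table <- function(x, ...) {
  cat(x$title, "\n\n")
  print.data.frame(x$rows, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' Write a rendered report's numeric results as CSV
#'
#' Writes the unrounded numbers behind a rendered table (the pretty
#' rendering is never the only artifact). Power-curve components are
#' written with their `person_years`, `odds_ratio` and CI columns;
#' expected-case components with per-decile counts.
#'
#' @param x A [render_paper_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "report_table"))
  d <- x$data
  if (is.data.frame(d)) {
    utils::write.csv(d, path, row.names = FALSE)
  } else if (!is.null(d$curve)) {
    utils::write.csv(as.data.frame(d$curve), path, row.names = FALSE)
  } else {
    est <- d[[1L]]
    utils::write.csv(data.frame(
      odds_ratio = vapply(d, function(e) e$odds_ratio, numeric(1L)),
      ci_lower = vapply(d, function(e) e$ci_lower, numeric(1L)),
      ci_upper = vapply(d, function(e) e$ci_upper, numeric(1L)),
      p_value = vapply(d, function(e) e$p_value, numeric(1L))),
      path, row.names = FALSE)
  }
  invisible(path)
}
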