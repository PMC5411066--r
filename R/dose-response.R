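#' Power-law dose-response curve for serum 25(OH)D and disease odds
#'
#' Constructs the curve mapping a serum 25-hydroxyvitamin D concentration
#' (ng/mL) to a disease odds ratio, `OR(c) = coefficient * c^exponent`.
#' The defaults (18.3, -0.833) describe breast-cancer incidence pooled over
#' case-control studies and are used as the all-cancer proxy throughout.
#'
#' The power law diverges as the concentration approaches zero, and the
#' relation is never used below about 11 ng/mL in practice, so evaluation is
#' restricted to concentrations at or above `min_concentration`; requests
#' below the floor are errors rather than clamps, to surface bad inputs.
#'
#' @param coefficient Positive multiplier on the odds-ratio scale.
#' @param exponent Power on concentration; negative values give a protective
#'   (decreasing) relation.
#' @param min_concentration Evaluation floor in ng/mL (default 1).
#' @return An object of class `dose_response_curve`.
#' @seealso [odds_ratio_at()], [fit_power_law()]
#' @examples
#' curve <- dose_response_curve()
#' odds_ratio_at(curve, c(11, 33))
#' @export
dose_response_curve <- function(coefficient = 18.3, exponent = -0.833,
                                min_concentration = 1) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient) || coefficient <= 0) {
    stop("`coefficient` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent)) {
    stop("`exponent` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(min_concentration) || length(min_concentration) != 1L ||
      !is.finite(min_concentration) || min_concentration <= 0) {
    stop("`min_concentration` must be a single positive number", call. = FALSE)
  }
  structure(
    list(coefficient = coefficient, exponent = exponent,
         min_concentration = min_concentration),
    class = "dose_response_curve"
  )
}

#' Evaluate a dose-response curve
#'
#' @param curve A [dose_response_curve()].
#' @param concentration Serum 25(OH)D in ng/mL; must be at or above the
#'   curve's evaluation floor. Vectorised.
#' @return Odds ratio(s), dimensionless and strictly positive.
#' @examples
#' odds_ratio_at(dose_response_curve(), 33)
#' @export
odds_ratio_at <- function(curve, concentration) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (!is.numeric(concentration) || length(concentration) < 1L ||
      any(!is.finite(concentration))) {
    stop("`concentration` must be finite and numeric", call. = FALSE)
  }
  if (any(concentration < curve$min_concentration)) {
    stop(sprintf(
      "concentration below the evaluation floor of %g ng/mL (got %g)",
      curve$min_concentration, min(concentration)), call. = FALSE)
  }
  curve$coefficient * concentration ^ curve$exponent
}

#' @param object A `dose_response_curve`.
#' @param concentration Concentrations (ng/mL) at which to evaluate.
#' @param ... Unused.
#' @rdname odds_ratio_at
#' @export
predict.dose_response_curve <- function(object, concentration, ...) {
  odds_ratio_at(object, concentration)
}

#' Fit a power-law dose-response curve to (concentration, odds ratio) points
#'
#' Least-squares fit of `log(OR)` on `log(concentration)`. Points lying
#' exactly on one power law are recovered exactly; otherwise the fit is the
#' usual log-log regression.
#'
#' @param concentration Concentrations in ng/mL, strictly positive.
#' @param odds_ratio Observed odds ratios, strictly positive, same length.
#' @param min_concentration Evaluation floor passed to the returned curve.
#' @return A [dose_response_curve()] with an attached `fit` element (the
#'   underlying `lm` object) retrievable via `attr(curve, "fit")`.
#' @examples
#' cc <- c(10, 20, 40)
#' fit_power_law(cc, 18.3 * cc^-0.833)
#' @export
fit_power_law <- function(concentration, odds_ratio, min_concentration = 1) {
  if (length(concentration) != length(odds_ratio)) {
    stop("`concentration` and `odds_ratio` must have equal length",
         call. = FALSE)
  }
  if (length(concentration) < 2L) {
    stop("at least 2 points are required to fit a power law", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0) ||
      any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("all concentrations and odds ratios must be strictly positive",
         call. = FALSE)
  }
  fit <- stats::lm(log(odds_ratio) ~ log(concentration))
  cf <- stats::coef(fit)
  curve <- dose_response_curve(
    coefficient = exp(unname(cf[1L])),
    exponent = unname(cf[2L]),
    min_concentration = min_concentration
  )
  attr(curve, "fit") <- fit
  curve
}

#' Convert ng/mL of 25(OH)D to nmol/L
#'
#' The SI conversion multiplies by 2.5. Never applied implicitly anywhere in
#' the package; all interfaces are in ng/mL.
#'
#' @param ng_ml Concentration(s) in ng/mL.
#' @return Concentration(s) in nmol/L.
#' @export
ng_ml_to_nmol_l <- function(ng_ml) 2.5 * ng_ml

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve: OR(c) = %.4g * c^%.4g  (c >= %g ng/mL)\n",
              x$coefficient, x$exponent, x$min_concentration))
  if (!is.null(attr(x, "fit"))) {
    cat(sprintf("  fitted by log-log least squares on %d points\n",
                length(stats::fitted(attr(x, "fit")))))
  }
  invisible(x)
}
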