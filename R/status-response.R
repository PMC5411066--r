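#' Calibration grid of achieved 25(OH)D by baseline and daily dose
#'
#' The default grid of achieved serum 25(OH)D concentrations (ng/mL) after
#' sustained daily vitamin D3 supplementation, for the ten decile baselines
#' of the reference (Canadian, ages 50-79) population and doses of 400,
#' 1000, 2000 and 4000 IU/d. Values derive from community-cohort
#' before/after supplementation measurements and are stored verbatim; the
#' grid contains one known non-monotone cell (baseline 11 ng/mL at
#' 400 IU/d exceeds baseline 14 ng/mL at 400 IU/d), which is preserved for
#' fidelity and reported by [check_calibration()] rather than corrected.
#'
#' @return A data frame with columns `baseline_ng_ml`, `dose_iu_d`,
#'   `achieved_ng_ml`, one row per grid cell.
#' @export
default_calibration_grid <- function() {
  baseline <- c(11, 14, 17, 20, 23, 26, 29, 33, 36, 40)
  achieved <- rbind(
    # dose:  400 1000 2000 4000
    c(25, 29, 31, 45),
    c(18, 24, 33, 47),
    c(21, 28, 35, 49),
    c(24, 29, 37, 50),
    c(27, 32, 40, 51),
    c(29, 35, 42, 53),
    c(33, 37, 44, 55),
    c(36, 40, 47, 57),
    c(39, 43, 49, 59),
    c(43, 46, 52, 61)
  )
  doses <- c(400, 1000, 2000, 4000)
  data.frame(
    baseline_ng_ml = rep(baseline, times = length(doses)),
    dose_iu_d = rep(doses, each = length(baseline)),
    achieved_ng_ml = as.vector(achieved)
  )
}

#' Validate a calibration grid
#'
#' Checks monotonicity of achieved concentration in baseline at fixed dose
#' and in dose at fixed baseline, and that achieved is at least baseline.
#'
#' @param grid A calibration data frame as from [default_calibration_grid()].
#' @return A character vector of anomaly descriptions (empty if clean).
#' @export
check_calibration <- function(grid) {
  anomalies <- character()
  for (d in sort(unique(grid$dose_iu_d))) {
    sub <- grid[grid$dose_iu_d == d, ]
    sub <- sub[order(sub$baseline_ng_ml), ]
    bad <- which(diff(sub$achieved_ng_ml) < 0)
    for (i in bad) {
      anomalies <- c(anomalies, sprintf(
        "achieved at %g IU/d decreases from %g to %g between baselines %g and %g ng/mL",
        d, sub$achieved_ng_ml[i], sub$achieved_ng_ml[i + 1L],
        sub$baseline_ng_ml[i], sub$baseline_ng_ml[i + 1L]))
    }
  }
  for (b in sort(unique(grid$baseline_ng_ml))) {
    sub <- grid[grid$baseline_ng_ml == b, ]
    sub <- sub[order(sub$dose_iu_d), ]
    if (any(diff(sub$achieved_ng_ml) < 0)) {
      anomalies <- c(anomalies, sprintf(
        "achieved decreases with dose at baseline %g ng/mL", b))
    }
    if (any(sub$achieved_ng_ml < b)) {
      anomalies <- c(anomalies, sprintf(
        "achieved below baseline at baseline %g ng/mL", b))
    }
  }
  anomalies
}

# Solve g(c) = A*exp(-c/tau) + B through three (concentration, increment)
# anchors with decreasing increments. Exact: root-find on tau.
solve_increment_anchors <- function(anchors) {
  c1 <- anchors[[1L]][1L]; g1 <- anchors[[1L]][2L]
  c2 <- anchors[[2L]][1L]; g2 <- anchors[[2L]][2L]
  c3 <- anchors[[3L]][1L]; g3 <- anchors[[3L]][2L]
  if (!(c1 < c2 && c2 < c3) || !(g1 > g2 && g2 > g3)) {
    stop("anchors must have increasing concentrations and strictly decreasing increments",
         call. = FALSE)
  }
  resid <- function(tau) {
    A <- (g1 - g2) / (exp(-c1 / tau) - exp(-c2 / tau))
    B <- g1 - A * exp(-c1 / tau)
    A * exp(-c3 / tau) + B - g3
  }
  tau <- stats::uniroot(resid, interval = c(1e-3, 1e4), tol = 1e-12)$root
  A <- (g1 - g2) / (exp(-c1 / tau) - exp(-c2 / tau))
  B <- g1 - A * exp(-c1 / tau)
  list(A = A, tau = tau, B = B)
}

#' Status-response model: achieved 25(OH)D from baseline and dose
#'
#' Two backends predict the achieved serum 25(OH)D concentration after
#' sustained daily vitamin D3 supplementation:
#'
#' * `"calibration"` — bilinear interpolation on a (baseline, dose) grid of
#'   measured achieved concentrations, exact at grid points, flat-clamped
#'   outside the grid. Canonical for reproducing the reference tables.
#' * `"parametric"` — integrates the per-dose increment function
#'   `g(c) = A exp(-c/tau) + B` (ng/mL rise per 1000 IU/d at current
#'   concentration `c`), with `(A, tau, B)` solved exactly from three
#'   anchors: a 13 ng/mL rise at concentration 0, 4 at 28 and 2 at
#'   140 ng/mL. The decline reflects the upregulation of the catabolic
#'   enzyme CYP24A1 with rising status. Use this backend for doses or
#'   baselines away from the calibration grid.
#'
#' Zero dose returns the baseline unchanged under either backend.
#'
#' @param backend `"calibration"` or `"parametric"`.
#' @param calibration Calibration data frame (columns `baseline_ng_ml`,
#'   `dose_iu_d`, `achieved_ng_ml`); default [default_calibration_grid()].
#' @param anchors List of three `c(concentration, rise_per_1000iu)` pairs
#'   for the parametric backend.
#' @param check If `TRUE`, run [check_calibration()] on the grid and emit a
#'   warning describing any anomalies (the default grid has one known
#'   non-monotone cell).
#' @return An object of class `status_response_model`.
#' @seealso [achieved()], [increment_per_1000iu()]
#' @examples
#' m <- status_response_model(check = FALSE)
#' achieved(m, baseline = 14, dose = 2000)
#' @export
status_response_model <- function(backend = c("calibration", "parametric"),
                                  calibration = default_calibration_grid(),
                                  anchors = list(c(0, 13), c(28, 4), c(140, 2)),
                                  check = TRUE) {
  backend <- match.arg(backend)
  model <- list(backend = backend)
  if (backend == "calibration") {
    needed <- c("baseline_ng_ml", "dose_iu_d", "achieved_ng_ml")
    if (!is.data.frame(calibration) || !all(needed %in% names(calibration))) {
      stop("`calibration` must be a data frame with columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    anomalies <- check_calibration(calibration)
    if (check && length(anomalies)) {
      warning("calibration grid anomalies (stored verbatim, not corrected):\n  ",
              paste(anomalies, collapse = "\n  "), call. = FALSE)
    }
    model$calibration <- calibration
    model$anomalies <- anomalies
  } else {
    if (!is.list(anchors) || length(anchors) != 3L) {
      stop("`anchors` must be a list of three (concentration, rise) pairs",
           call. = FALSE)
    }
    model$anchors <- anchors
    model$params <- solve_increment_anchors(anchors)
  }
  class(model) <- "status_response_model"
  model
}

#' Rise in 25(OH)D per 1000 IU/d at a given current concentration
#'
#' The parametric backend's increment function: smooth, positive and
#' non-increasing in concentration, passing exactly through the model's
#' three anchors.
#'
#' @param model A parametric [status_response_model()].
#' @param concentration Current serum 25(OH)D in ng/mL (>= 0). Vectorised.
#' @return Rise in ng/mL per 1000 IU/d of daily vitamin D3.
#' @export
increment_per_1000iu <- function(model, concentration) {
  stopifnot(inherits(model, "status_response_model"))
  if (model$backend != "parametric") {
    stop("increment_per_1000iu() requires the parametric backend; ",
         "the calibration backend has no increment function", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("`concentration` must be non-negative", call. = FALSE)
  }
  p <- model$params
  p$A * exp(-concentration / p$tau) + p$B
}

# one RK4 step of dc/dD = g(c)/1000 over a dose increment h (IU/d)
rk4_step <- function(model, c0, h) {
  f <- function(c) increment_per_1000iu(model, c) / 1000
  k1 <- f(c0)
  k2 <- f(c0 + h / 2 * k1)
  k3 <- f(c0 + h / 2 * k2)
  k4 <- f(c0 + h * k3)
  c0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

achieved_parametric <- function(model, baseline, dose, step = 100) {
  n_full <- floor(dose / step)
  rem <- dose - n_full * step
  conc <- baseline
  if (n_full > 0) for (i in seq_len(n_full)) conc <- rk4_step(model, conc, step)
  if (rem > 0) conc <- rk4_step(model, conc, rem)
  conc
}

achieved_calibration <- function(model, baseline, dose, interpolate = TRUE) {
  grid <- model$calibration
  bases <- sort(unique(grid$baseline_ng_ml))
  doses <- sort(unique(grid$dose_iu_d))
  # dose 0 column is the identity (achieved = baseline)
  all_doses <- c(0, doses)
  value_at <- function(b, d) {
    if (d == 0) return(b)
    hit <- grid$achieved_ng_ml[grid$baseline_ng_ml == b & grid$dose_iu_d == d]
    hit[1L]
  }
  if (!interpolate && !(dose %in% all_doses && baseline %in% bases)) {
    stop(sprintf(
      "dose %g IU/d, baseline %g ng/mL is not a calibration grid point and interpolation is disabled (grid doses: %s)",
      dose, baseline, paste(all_doses, collapse = ", ")), call. = FALSE)
  }
  # flat clamp outside the grid
  b <- min(max(baseline, min(bases)), max(bases))
  d <- min(max(dose, 0), max(all_doses))
  b_lo <- max(bases[bases <= b]); b_hi <- min(bases[bases >= b])
  d_lo <- max(all_doses[all_doses <= d]); d_hi <- min(all_doses[all_doses >= d])
  interp <- function(x, x0, x1, y0, y1) {
    if (x1 == x0) y0 else y0 + (y1 - y0) * (x - x0) / (x1 - x0)
  }
  v_lo <- interp(d, d_lo, d_hi, value_at(b_lo, d_lo), value_at(b_lo, d_hi))
  v_hi <- interp(d, d_lo, d_hi, value_at(b_hi, d_lo), value_at(b_hi, d_hi))
  interp(b, b_lo, b_hi, v_lo, v_hi)
}

#' Achieved 25(OH)D concentration for a baseline and daily dose
#'
#' @param model A [status_response_model()].
#' @param baseline Baseline serum 25(OH)D in ng/mL (> 0). Vectorised.
#' @param dose Daily vitamin D3 dose in IU/d (>= 0), scalar.
#' @param interpolate Calibration backend only: if `FALSE`, querying off the
#'   grid is an error instead of bilinear interpolation.
#' @param step Parametric backend only: dose integration step in IU/d.
#' @return Achieved concentration(s) in ng/mL.
#' @examples
#' m <- status_response_model(check = FALSE)
#' achieved(m, 14, 2000)   # calibration grid point -> 33
#' @export
achieved <- function(model, baseline, dose, interpolate = TRUE, step = 100) {
  stopifnot(inherits(model, "status_response_model"))
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("`baseline` must be strictly positive", call. = FALSE)
  }
  if (length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("`dose` must be a single non-negative number of IU/d", call. = FALSE)
  }
  if (dose == 0) return(baseline)
  if (model$backend == "calibration") {
    vapply(baseline, achieved_calibration, numeric(1L),
           model = model, dose = dose, interpolate = interpolate)
  } else {
    vapply(baseline, achieved_parametric, numeric(1L),
           model = model, dose = dose, step = step)
  }
}

#' Read or write a calibration grid as CSV
#'
#' Plain CSV with columns `baseline_ng_ml`, `dose_iu_d`, `achieved_ng_ml`.
#'
#' @param path File path.
#' @return `read_calibration()` returns the grid data frame;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  grid <- utils::read.csv(path)
  needed <- c("baseline_ng_ml", "dose_iu_d", "achieved_ng_ml")
  if (!all(needed %in% names(grid))) {
    stop("calibration CSV must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  grid[needed]
}

#' @param grid A calibration data frame.
#' @rdname read_calibration
#' @export
write_calibration <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.status_response_model <- function(x, ...) {
  cat("Status-response model (achieved 25(OH)D from baseline + dose)\n")
  if (x$backend == "calibration") {
    cat(sprintf("  backend: calibration table, %d cells (doses %s IU/d)\n",
                nrow(x$calibration),
                paste(sort(unique(x$calibration$dose_iu_d)), collapse = "/")))
    if (length(x$anomalies)) {
      cat("  grid anomalies:", length(x$anomalies), "(see check_calibration)\n")
    }
  } else {
    p <- x$params
    cat(sprintf("  backend: parametric, rise/1000 IU/d = %.3f*exp(-c/%.3f) + %.3f ng/mL\n",
                p$A, p$tau, p$B))
  }
  invisible(x)
}
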