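#' Fit the pulse-energy to impulsive-force calibration
#'
#' Ordinary least-squares fit of total impulsive force F0 (uN) on laser pulse
#' energy L (nJ/pulse), from an AFM-style calibration table.  The physical
#' boundary condition (zero energy delivers zero force) motivates the default
#' through-origin constraint; an affine fit is available for diagnostics.
#'
#' @param records data frame with columns `pulse_energy_nJ` and
#'   `total_force_uN`, one row per calibration measurement.
#' @param through_origin constrain the intercept to zero (default `TRUE`).
#' @return An object of class `calibration_model` with fields
#'   `slope_uN_per_nJ`, `intercept_uN`, `fitted_energy_range_nJ`,
#'   `r_squared` (squared Pearson correlation of force with energy) and
#'   `n_points`.
#' @examples
#' tab <- gen_calibration_table(10, slope_uN_per_nJ = 0.02, seed = 1)
#' fit_calibration(tab)
#' @export
fit_calibration <- function(records, through_origin = TRUE) {
  records <- as.data.frame(records)
  if (!all(c("pulse_energy_nJ", "total_force_uN") %in% names(records)))
    abort_invalid("calibration records need columns pulse_energy_nJ and total_force_uN")
  L <- records$pulse_energy_nJ
  F0 <- records$total_force_uN
  if (!all(is.finite(L)) || !all(is.finite(F0)))
    abort_invalid("calibration records contain non-finite values")
  if (any(L <= 0)) abort_invalid("pulse energies must be positive")
  n_min <- if (through_origin) 2L else 3L
  if (length(L) < n_min)
    abort_invalid("need at least ", n_min, " calibration records")
  if (length(unique(L)) < 2L)
    abort_invalid("degenerate fit: all pulse energies identical")

  fit <- if (through_origin) lm(F0 ~ 0 + L) else lm(F0 ~ L)
  cf <- coef(fit)
  slope <- unname(if (through_origin) cf[["L"]] else cf[["L"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (slope <= 0)
    abort_inference("calibration-quality error: fitted slope is not positive")

  r2 <- if (sd(F0) == 0) 1 else unname(stats::cor(L, F0)^2)
  structure(
    list(slope_uN_per_nJ = slope,
         intercept_uN = intercept,
         fitted_energy_range_nJ = range(L),
         r_squared = r2,
         n_points = length(L),
         through_origin = through_origin),
    class = "calibration_model")
}

#' Convert laser pulse energy to total impulsive force
#'
#' Applies a fitted calibration model F0 = slope * L + intercept.  Energies
#' outside the fitted range are still converted but flagged: a warning is
#' emitted and the result carries an `extrapolated` attribute.
#'
#' @param model a `calibration_model` from [fit_calibration()] or
#'   [calibration_model()].
#' @param pulse_energy_nJ vector of pulse energies (nJ/pulse), all positive.
#' @return numeric vector of total forces (uN), with attribute
#'   `extrapolated`: logical vector marking energies outside the fitted range.
#' @export
force_from_energy <- function(model, pulse_energy_nJ) {
  if (!inherits(model, "calibration_model"))
    abort_invalid("state error: model is not a fitted calibration_model")
  if (any(!is.finite(pulse_energy_nJ)) || any(pulse_energy_nJ <= 0))
    abort_invalid("pulse energies must be positive and finite")
  force <- model$slope_uN_per_nJ * pulse_energy_nJ + model$intercept_uN
  rng <- model$fitted_energy_range_nJ
  extra <- pulse_energy_nJ < rng[1] | pulse_energy_nJ > rng[2]
  if (any(extra))
    warning(sum(extra), " pulse energy value(s) outside the fitted range [",
            rng[1], ", ", rng[2], "] nJ; calibration extrapolated",
            call. = FALSE)
  attr(force, "extrapolated") <- extra
  force
}

#' Construct a calibration model from known coefficients
#'
#' Useful when the calibration line is specified rather than fitted, e.g. for
#' synthetic-data ground truth.
#'
#' @param slope_uN_per_nJ positive slope (uN per nJ).
#' @param intercept_uN intercept (uN), default 0.
#' @param fitted_energy_range_nJ energy interval the model is trusted over.
#' @return a `calibration_model`.
#' @export
calibration_model <- function(slope_uN_per_nJ, intercept_uN = 0,
                              fitted_energy_range_nJ = c(10, 60)) {
  if (!is.finite(slope_uN_per_nJ) || slope_uN_per_nJ <= 0)
    abort_invalid("slope must be positive")
  structure(
    list(slope_uN_per_nJ = slope_uN_per_nJ,
         intercept_uN = intercept_uN,
         fitted_energy_range_nJ = sort(fitted_energy_range_nJ),
         r_squared = NA_real_,
         n_points = 0L,
         through_origin = intercept_uN == 0),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Pulse-energy -> impulsive-force calibration (F0 = slope * L",
      if (!x$through_origin) "+ intercept", ")\n")
  cat(sprintf("  slope: %.6g uN/nJ   intercept: %.6g uN\n",
              x$slope_uN_per_nJ, x$intercept_uN))
  cat(sprintf("  fitted over L in [%g, %g] nJ  (n = %d, r^2 = %.3f)\n",
              x$fitted_energy_range_nJ[1], x$fitted_energy_range_nJ[2],
              x$n_points, x$r_squared))
  invisible(x)
}

#' Read / write calibration artifacts
#'
#' Calibration tables are CSV with header `pulse_energy_nJ,total_force_uN`;
#' fitted models are JSON with unit-suffixed field names.
#'
#' @param path file path.
#' @return `read_calibration_table`: a data frame; `read_calibration_model`:
#'   a `calibration_model`.
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @param records calibration data frame.
#' @export
write_calibration_table <- function(records, path) {
  write.csv(as.data.frame(records)[, c("pulse_energy_nJ", "total_force_uN")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("pulse_energy_nJ", "total_force_uN") %in% names(tab)))
    abort_invalid("not a calibration table: ", path)
  tab
}

#' @rdname calibration_io
#' @param model a `calibration_model`.
#' @export
write_calibration_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "calibration_model")
}
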