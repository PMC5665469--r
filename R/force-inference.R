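#' Pressure at a distance under spherical volume-wave propagation
#'
#' A short-lived impulsive force of total magnitude F0 generated at the laser
#' focal point is assumed to propagate spherically as a volume wave, so at
#' distance R the force is spread over the sphere surface 4*pi*R^2 and the
#' pressure is P = F0 / (4 * pi * R^2).  With F0 in uN and R in um the raw
#' quotient is in uN/um^2 = 1e6 Pa; the result is returned in kPa.
#'
#' @param total_force_uN total impulsive force at the focal point (uN).
#' @param radius_um distance from the focal point (um); here the
#'   counter-balanced ring radius.
#' @param geometry_factor surface-area factor of the propagation geometry;
#'   default `4 * pi` (full sphere).
#' @return pressure in kPa.
#' @examples
#' point_pressure(4 * pi, 1)  # 1 uN/um^2 = 1e6 Pa = 1000 kPa
#' @export
point_pressure <- function(total_force_uN, radius_um,
                           geometry_factor = 4 * pi) {
  if (any(!is.finite(total_force_uN)) || any(total_force_uN <= 0))
    abort_invalid("total force must be positive and finite")
  if (any(!is.finite(radius_um)) || any(radius_um < 0))
    abort_invalid("radius must be non-negative and finite")
  if (any(radius_um == 0))
    abort_invalid("singularity: pressure diverges at radius 0")
  total_force_uN / (geometry_factor * radius_um^2) * .kpa_per_uN_um2
}

#' Fit the counter-balance line R^2 = a * F0
#'
#' Converts each observation's pulse energy L to total force F0 through the
#' calibration model, then regresses the squared counter-balanced radius R^2
#' (um^2) on F0 (uN) by ordinary least squares.  The through-origin default
#' encodes the boundary condition R^2 = 0 at F0 = 0; the affine alternative
#' reports an intercept for diagnostics (the pressure conversion uses only
#' the slope).
#'
#' @param observations data frame with columns `condition`,
#'   `pulse_energy_nJ`, `radius_um` (one condition per call).
#' @param calib a `calibration_model`.
#' @param through_origin constrain the fit through the origin (default).
#' @return a `balance_fit` with `slope_a_um2_per_uN`, `intercept_um2`,
#'   `r_squared` (squared Pearson correlation of R^2 with F0), `n`,
#'   `condition`.
#' @export
fit_balance_line <- function(observations, calib, through_origin = TRUE) {
  observations <- as.data.frame(observations)
  need <- c("condition", "pulse_energy_nJ", "radius_um")
  if (!all(need %in% names(observations)))
    abort_invalid("observations need columns ", paste(need, collapse = ", "))
  cond <- unique(as.character(observations$condition))
  if (length(cond) != 1L)
    abort_invalid("mixed conditions in one balance fit: ",
                  paste(cond, collapse = ", "))
  if (nrow(observations) < 3L)
    abort_invalid("need at least 3 counter-balance observations")
  if (length(unique(observations$pulse_energy_nJ)) < 2L)
    abort_invalid("observations span a single pulse energy; slope unidentifiable")
  if (any(observations$radius_um < 0))
    abort_invalid("radii must be non-negative")

  force <- suppressWarnings(force_from_energy(calib, observations$pulse_energy_nJ))
  r2obs <- observations$radius_um^2
  fit <- if (through_origin) lm(r2obs ~ 0 + force) else lm(r2obs ~ force)
  slope <- unname(coef(fit)[["force"]])
  intercept <- if (through_origin) 0 else unname(coef(fit)[["(Intercept)"]])
  if (slope <= 0)
    abort_inference("counter-balance model violated: fitted slope <= 0")
  r_sq <- if (sd(r2obs) == 0) 1 else unname(stats::cor(force, r2obs)^2)
  structure(
    list(slope_a_um2_per_uN = slope,
         intercept_um2 = intercept,
         r_squared = r_sq,
         n = nrow(observations),
         condition = cond,
         through_origin = through_origin),
    class = "balance_fit")
}

#' Convert the balance-line slope to a contractile pressure
#'
#' Inverts the spherical propagation law: on the balance line R^2 = a * F0,
#' every datum satisfies P = F0 / (4*pi*R^2) = 1 / (4*pi*a), so the slope a
#' (um^2/uN) maps to a single pressure, returned in kPa.
#'
#' @param fit a `balance_fit` from [fit_balance_line()].
#' @param geometry_factor propagation geometry factor, default `4 * pi`.
#' @return a `pressure_estimate` with `pressure_kPa`, `method = "slope"` and
#'   (unfilled) CI fields.
#' @examples
#' # slope 21.45 um^2/uN corresponds to about 3.71 kPa
#' fit <- structure(list(slope_a_um2_per_uN = 21.45, condition = "control"),
#'                  class = "balance_fit")
#' pressure_from_slope(fit)
#' @export
pressure_from_slope <- function(fit, geometry_factor = 4 * pi) {
  if (!inherits(fit, "balance_fit")) abort_invalid("fit must be a balance_fit")
  a <- fit$slope_a_um2_per_uN
  if (!is.finite(a) || a <= 0)
    abort_inference("slope must be positive to infer a pressure")
  p <- 1 / (geometry_factor * a) * .kpa_per_uN_um2
  structure(
    list(pressure_kPa = p,
         ci_95_kPa = c(NA_real_, NA_real_),
         method = "slope",
         n_boot = 0L,
         seed = NA_integer_,
         condition = fit$condition %||% NA_character_),
    class = "pressure_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap confidence interval for the contractile pressure
#'
#' Case-resampling bootstrap over counter-balance observations: each resample
#' is refitted ([fit_balance_line()]) and converted
#' ([pressure_from_slope()]); the point estimate comes from the full data and
#' the 95% CI from the percentile method.  Resamples with a degenerate design
#' (a single distinct pulse energy) are redrawn, up to 100 retries each.
#'
#' @inheritParams fit_balance_line
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed; the draw is reproducible per seed.
#' @param geometry_factor propagation geometry factor, default `4 * pi`.
#' @return a `pressure_estimate` with percentile `ci_95_kPa`.
#' @export
bootstrap_pressure <- function(observations, calib, n_boot = 2000L, seed = 1L,
                               through_origin = TRUE,
                               geometry_factor = 4 * pi) {
  observations <- as.data.frame(observations)
  if (nrow(observations) < 5L)
    abort_invalid("need at least 5 observations to bootstrap")
  full <- fit_balance_line(observations, calib, through_origin)
  est <- pressure_from_slope(full, geometry_factor)

  n <- nrow(observations)
  force <- suppressWarnings(force_from_energy(calib,
                                              observations$pulse_energy_nJ))
  r2obs <- observations$radius_um^2
  boot <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(observations$pulse_energy_nJ[idx])) >= 2L) break
      if (try == 100L)
        abort_inference("bootstrap design degenerate after 100 redraws")
    }
    # same least-squares estimator as fit_balance_line, in closed form
    x <- force[idx]; y <- r2obs[idx]
    a <- if (through_origin) sum(x * y) / sum(x * x)
         else (sum(x * y) - sum(x) * sum(y) / n) / (sum(x^2) - sum(x)^2 / n)
    boot[b] <- if (a > 0) 1 / (geometry_factor * a) * .kpa_per_uN_um2
               else NA_real_
  }
  boot <- boot[is.finite(boot)]
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  structure(
    list(pressure_kPa = est$pressure_kPa,
         ci_95_kPa = ci,
         method = "slope",
         n_boot = as.integer(n_boot),
         seed = as.integer(seed),
         condition = full$condition),
    class = "pressure_estimate")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.balance_fit <- function(x, ...) {
  cat(sprintf("Counter-balance fit (%s): R^2 = %.4g * F0%s\n", x$condition,
              x$slope_a_um2_per_uN,
              if (x$through_origin) "" else sprintf(" + %.4g", x$intercept_um2)))
  cat(sprintf("  n = %d, correlation r^2 = %.3f\n", x$n, x$r_squared))
  invisible(x)
}

#' @export
print.pressure_estimate <- function(x, ...) {
  cat(sprintf("Contractile pressure: %.3f kPa", x$pressure_kPa))
  if (all(is.finite(x$ci_95_kPa)))
    cat(sprintf("  (95%% CI %.3f-%.3f, %d bootstrap resamples)",
                x$ci_95_kPa[1], x$ci_95_kPa[2], x$n_boot))
  cat("\n")
  invisible(x)
}

#' Read / write counter-balance observations and pressure results
#'
#' Observations are CSV with header `condition,pulse_energy_nJ,radius_um`;
#' a pressure result (estimate plus its balance fit) is a single JSON file
#' with unit-suffixed field names.
#'
#' @param path file path.
#' @name inference_io
NULL

#' @rdname inference_io
#' @param observations counter-balance data frame.
#' @export
write_counterbalance_table <- function(observations, path) {
  write.csv(as.data.frame(observations)[, c("condition", "pulse_energy_nJ",
                                            "radius_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname inference_io
#' @export
read_counterbalance_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("condition", "pulse_energy_nJ", "radius_um") %in% names(tab)))
    abort_invalid("not a counter-balance table: ", path)
  tab
}

#' @rdname inference_io
#' @param estimate a `pressure_estimate`.
#' @param fit the `balance_fit` it came from (optional).
#' @export
write_pressure_result <- function(estimate, path, fit = NULL) {
  out <- list(pressure = unclass(estimate))
  if (!is.null(fit)) out$balance_fit <- unclass(fit)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname inference_io
#' @export
read_pressure_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pressure <- structure(x$pressure, class = "pressure_estimate")
  if (!is.null(x$balance_fit))
    x$balance_fit <- structure(x$balance_fit, class = "balance_fit")
  x
}
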