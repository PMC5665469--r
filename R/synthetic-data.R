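#' Generate a synthetic pulse-energy / impulsive-force calibration table
#'
#' Emulates an AFM-cantilever calibration of the laser-induced impulsive
#' force: total force F0 (uN) is a near-linear function of pulse energy L
#' (nJ/pulse) with additive Gaussian measurement noise,
#' `F0 = slope * L + intercept + N(0, noise_sd)`.
#'
#' @param n_points number of calibration measurements (>= 2), evenly spaced
#'   over `energy_range_nJ`.
#' @param slope_uN_per_nJ true slope (uN per nJ), positive.
#' @param intercept_uN true intercept (uN), default 0.
#' @param noise_sd_uN Gaussian measurement noise sd (uN).
#' @param energy_range_nJ pulse-energy interval (nJ/pulse), default 10-60.
#' @param seed integer seed; output is reproducible per seed.
#' @return data frame with columns `pulse_energy_nJ`, `total_force_uN`.
#' @export
gen_calibration_table <- function(n_points = 20L, slope_uN_per_nJ = 0.02,
                                  intercept_uN = 0, noise_sd_uN = 0.05,
                                  energy_range_nJ = c(10, 60), seed = 1L) {
  if (n_points < 2L) abort_invalid("need n_points >= 2")
  if (!is.finite(slope_uN_per_nJ) || slope_uN_per_nJ <= 0)
    abort_invalid("slope must be positive")
  if (length(energy_range_nJ) != 2L || diff(energy_range_nJ) <= 0 ||
      energy_range_nJ[1] <= 0)
    abort_invalid("energy range must be a positive, non-empty interval")
  if (noise_sd_uN < 0) abort_invalid("noise sd must be non-negative")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  L <- seq(energy_range_nJ[1], energy_range_nJ[2], length.out = n_points)
  F0 <- slope_uN_per_nJ * L + intercept_uN + rnorm(n_points, 0, noise_sd_uN)
  data.frame(pulse_energy_nJ = L, total_force_uN = F0)
}

#' Generate synthetic counter-balance observations
#'
#' Emulates the loading experiment under a known ground-truth contractile
#' pressure: at pulse energy L the total force is F0 (via the calibration
#' model) and the noiseless counter-balanced radius satisfies the spherical
#' propagation law `R = sqrt(F0 / (4*pi*P_true))` (units: um, uN, with
#' P_true converted from kPa to uN/um^2).  Multiplicative Gaussian
#' measurement noise is applied to R: `R_obs = R * (1 + N(0, noise_cv))`.
#'
#' @param pressure_true_kPa ground-truth contractile pressure (kPa), positive.
#' @param energies_nJ pulse energies to load (nJ/pulse); each is replicated
#'   `n_reps` times.
#' @param calib a `calibration_model` mapping L to F0.
#' @param noise_cv coefficient of variation of the radius measurement
#'   (default 0.1).
#' @param n_reps replicates per energy (default 1).
#' @param seed integer seed.
#' @param condition condition label attached to every observation.
#' @param geometry_factor propagation geometry factor, default `4 * pi`.
#' @return data frame with columns `condition`, `pulse_energy_nJ`,
#'   `radius_um`.
#' @export
gen_counterbalance_set <- function(pressure_true_kPa,
                                   energies_nJ = seq(10, 60, by = 5),
                                   calib = calibration_model(0.02),
                                   noise_cv = 0.1, n_reps = 1L, seed = 1L,
                                   condition = "control",
                                   geometry_factor = 4 * pi) {
  if (!is.finite(pressure_true_kPa) || pressure_true_kPa <= 0)
    abort_invalid("ground-truth pressure must be positive")
  if (noise_cv < 0) abort_invalid("noise_cv must be non-negative")
  if (n_reps < 1L) abort_invalid("n_reps must be >= 1")
  L <- rep(energies_nJ, each = n_reps)
  F0 <- as.numeric(suppressWarnings(force_from_energy(calib, L)))
  p_uN_um2 <- pressure_true_kPa / .kpa_per_uN_um2
  R <- sqrt(F0 / (geometry_factor * p_uN_um2))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  R_obs <- pmax(R * (1 + rnorm(length(R), 0, noise_cv)), 0)
  data.frame(condition = condition, pulse_energy_nJ = L, radius_um = R_obs)
}

#' Generate synthetic extrusion-completion cohorts
#'
#' Completion times are Gaussian: control `N(mean, sd)`, treated
#' `N(mean + delay, sd)` — emulating the delay of cell extrusion under
#' partial actomyosin inhibition.
#'
#' @param n_per_group cells per group (>= 2).
#' @param mean_completion_s control mean completion time (s after
#'   induction), default 300.
#' @param sd_s between-cell sd (s), default 20.
#' @param delay_s treatment-induced delay (s), default 100.
#' @param seed integer seed.
#' @param treated_condition label of the treated group.
#' @return data frame with columns `condition`, `completion_time_s`.
#' @export
gen_extrusion_cohort <- function(n_per_group, mean_completion_s = 300,
                                 sd_s = 20, delay_s = 100, seed = 1L,
                                 treated_condition = "Y27632") {
  if (n_per_group < 2L) abort_invalid("need n_per_group >= 2")
  if (sd_s < 0) abort_invalid("sd must be non-negative")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ctrl <- rnorm(n_per_group, mean_completion_s, sd_s)
  trt <- rnorm(n_per_group, mean_completion_s + delay_s, sd_s)
  data.frame(
    condition = rep(c("control", treated_condition), each = n_per_group),
    completion_time_s = c(ctrl, trt))
}

#' Read / write extrusion cohort tables
#'
#' CSV with header `condition,completion_time_s`.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @name cohort_io
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(as.data.frame(cohort)[, c("condition", "completion_time_s")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("condition", "completion_time_s") %in% names(tab)))
    abort_invalid("not a cohort table: ", path)
  tab
}
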