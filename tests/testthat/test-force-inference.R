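test_that("point pressure implements the spherical propagation law and units", {
  # F0 = 4*pi uN at R = 1 um is exactly 1 uN/um^2 = 1e6 Pa = 1000 kPa
  expect_equal(point_pressure(4 * pi, 1), 1000, tolerance = 1e-12)
  # F0 = 1 uN at R = 10 um: 1/(400*pi) uN/um^2 ~ 0.79577 kPa
  expect_equal(point_pressure(1, 10), 1000 / (400 * pi), tolerance = 1e-12)
  expect_equal(point_pressure(1, 10), 0.7957747, tolerance = 1e-6)
  # homogeneity: linear in force, inverse-square in radius
  expect_equal(point_pressure(2 * 1.2, 4), 2 * point_pressure(1.2, 4))
  expect_equal(point_pressure(1.2, 2 * 4), point_pressure(1.2, 4) / 4)
  expect_error(point_pressure(1, 0), class = "ringforce_invalid_input")
  expect_error(point_pressure(-1, 2), class = "ringforce_invalid_input")
})

test_that("noise-free observations are inverted exactly by the balance fit", {
  cal <- calibration_model(0.02)
  for (p_true in c(1, 2.40, 2.58, 3.71, 10)) {
    obs <- gen_counterbalance_set(p_true, seq(10, 60, 5), cal, noise_cv = 0,
                                  seed = 1)
    fit <- fit_balance_line(obs, cal)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_equal(fit$slope_a_um2_per_uN, 1000 / (4 * pi * p_true),
                 tolerance = 1e-10)
    expect_equal(pressure_from_slope(fit)$pressure_kPa, p_true,
                 tolerance = 1e-10)
  }
})

test_that("the balance-line slope matches the normal-equations oracle", {
  cal <- calibration_model(0.02)
  obs <- gen_counterbalance_set(3.71, seq(10, 60, 5), cal, noise_cv = 0.1,
                                n_reps = 3, seed = 8)
  f0 <- 0.02 * obs$pulse_energy_nJ
  fit0 <- fit_balance_line(obs, cal, through_origin = TRUE)
  expect_equal(fit0$slope_a_um2_per_uN, ols_slope_origin(f0, obs$radius_um^2),
               tolerance = 1e-10)
  fit1 <- fit_balance_line(obs, cal, through_origin = FALSE)
  oracle <- ols_affine(f0, obs$radius_um^2)
  expect_equal(fit1$slope_a_um2_per_uN, unname(oracle["slope"]),
               tolerance = 1e-10)
  expect_equal(fit1$intercept_um2, unname(oracle["intercept"]),
               tolerance = 1e-10)
})

test_that("balance fits validate their design", {
  cal <- calibration_model(0.02)
  one_energy <- data.frame(condition = "control",
                           pulse_energy_nJ = c(30, 30, 30),
                           radius_um = c(3, 3.1, 2.9))
  expect_error(fit_balance_line(one_energy, cal),
               class = "ringforce_invalid_input")
  mixed <- data.frame(condition = c("control", "Y27632", "control"),
                      pulse_energy_nJ = c(10, 30, 50),
                      radius_um = c(2, 3, 4))
  expect_error(fit_balance_line(mixed, cal),
               class = "ringforce_invalid_input")
  falling <- data.frame(condition = "control",
                        pulse_energy_nJ = c(10, 30, 50),
                        radius_um = c(4, 3, 1e-3))
  expect_error(fit_balance_line(falling, cal, through_origin = FALSE),
               class = "ringforce_inference_error")
})

test_that("slope conversion and pointwise pressure agree on exact data", {
  # algebraic identity linking the propagation law and its slope inversion
  expect_equal(pressure_from_slope(
    structure(list(slope_a_um2_per_uN = 1 / (4 * pi)), class = "balance_fit")
  )$pressure_kPa, 1000, tolerance = 1e-12)
  expect_equal(pressure_from_slope(
    structure(list(slope_a_um2_per_uN = 21.45), class = "balance_fit")
  )$pressure_kPa, 1000 / (4 * pi * 21.45), tolerance = 1e-12)

  cal <- calibration_model(0.02)
  obs <- gen_counterbalance_set(2.58, seq(10, 60, 5), cal, noise_cv = 0,
                                seed = 2)
  fit <- fit_balance_line(obs, cal)
  p_slope <- pressure_from_slope(fit)$pressure_kPa
  f0 <- 0.02 * obs$pulse_energy_nJ
  p_point <- point_pressure(f0, obs$radius_um)
  expect_equal(p_point, rep(p_slope, length(p_point)), tolerance = 1e-10)

  expect_error(pressure_from_slope(
    structure(list(slope_a_um2_per_uN = -1), class = "balance_fit")),
    class = "ringforce_inference_error")
})

test_that("estimated pressure scales inversely with the square of the radii", {
  cal <- calibration_model(0.02)
  obs <- gen_counterbalance_set(3.71, seq(10, 60, 5), cal, noise_cv = 0.1,
                                seed = 3)
  p1 <- pressure_from_slope(fit_balance_line(obs, cal))$pressure_kPa
  obs$radius_um <- obs$radius_um * 1.7
  p2 <- pressure_from_slope(fit_balance_line(obs, cal))$pressure_kPa
  expect_equal(p2, p1 / 1.7^2, tolerance = 1e-10)
})

test_that("the through-origin estimator recovers known pressures on average", {
  cal <- calibration_model(0.02)
  for (p_true in c(1, 2.40, 2.58, 3.71, 10)) {
    est <- vapply(seq_len(100), function(rep) {
      set.seed(20000 + rep)
      energies <- runif(30, 10, 60)
      obs <- gen_counterbalance_set(p_true, energies, cal, noise_cv = 0.1,
                                    seed = 30000 + rep)
      pressure_from_slope(fit_balance_line(obs, cal))$pressure_kPa
    }, numeric(1))
    expect_lt(abs(mean(est) - p_true) / p_true, 0.05)
  }
})

test_that("bootstrap pressure CIs are reproducible and degenerate without noise", {
  cal <- calibration_model(0.02)
  exact <- gen_counterbalance_set(3.71, seq(10, 60, 5), cal, noise_cv = 0,
                                  seed = 1)
  ci <- bootstrap_pressure(exact, cal, n_boot = 200, seed = 5)
  expect_lt(diff(ci$ci_95_kPa), 1e-9)
  expect_equal(ci$pressure_kPa, 3.71, tolerance = 1e-10)

  noisy <- gen_counterbalance_set(3.71, seq(10, 60, 5), cal, noise_cv = 0.1,
                                  n_reps = 3, seed = 6)
  a <- bootstrap_pressure(noisy, cal, n_boot = 300, seed = 9)
  b <- bootstrap_pressure(noisy, cal, n_boot = 300, seed = 9)
  expect_identical(a$ci_95_kPa, b$ci_95_kPa)
  expect_true(a$ci_95_kPa[1] <= a$pressure_kPa &&
              a$pressure_kPa <= a$ci_95_kPa[2])
  expect_error(bootstrap_pressure(noisy[1:4, ], cal),
               class = "ringforce_invalid_input")
})

test_that("bootstrap CIs cover the generating pressure at near-nominal rate", {
  cal <- calibration_model(0.02)
  covered <- vapply(seq_len(100), function(rep) {
    obs <- gen_counterbalance_set(3.71, seq(10, 60, by = 2.5), cal,
                                  noise_cv = 0.1, seed = 40000 + rep)
    ci <- bootstrap_pressure(obs, cal, n_boot = 400, seed = 50000 + rep)
    ci$ci_95_kPa[1] <= 3.71 && 3.71 <= ci$ci_95_kPa[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
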