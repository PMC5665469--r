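test_that("zero-noise calibration tables lie exactly on the generating line", {
  tab <- gen_calibration_table(5, slope_uN_per_nJ = 0.02, intercept_uN = 0,
                               noise_sd_uN = 0, energy_range_nJ = c(10, 60),
                               seed = 1)
  expect_equal(tab$total_force_uN, 0.02 * tab$pulse_energy_nJ,
               tolerance = 1e-12)
  expect_identical(tab, gen_calibration_table(5, 0.02, 0, 0, c(10, 60), 1))
})

test_that("noisy calibration tables have the declared statistical structure", {
  tab <- gen_calibration_table(200, slope_uN_per_nJ = 0.02, noise_sd_uN = 0.05,
                               seed = 3)
  # closed-form OLS slope and its standard error as the oracle
  x <- tab$pulse_energy_nJ; y <- tab$total_force_uN
  cf <- ols_affine(x, y)
  sxx <- sum((x - mean(x))^2)
  resid <- y - cf["intercept"] - cf["slope"] * x
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  expect_lt(abs(cf[["slope"]] - 0.02), 3 * se)
})

test_that("calibration generator rejects invalid specifications", {
  expect_error(gen_calibration_table(1), class = "ringforce_invalid_input")
  expect_error(gen_calibration_table(5, slope_uN_per_nJ = -1),
               class = "ringforce_invalid_input")
  expect_error(gen_calibration_table(5, energy_range_nJ = c(10, 10)),
               class = "ringforce_invalid_input")
})

test_that("zero-noise counter-balance observations invert the propagation law", {
  cal <- calibration_model(0.02)
  obs <- gen_counterbalance_set(3.71, seq(10, 60, 5), cal, noise_cv = 0,
                                seed = 1)
  f0 <- 0.02 * obs$pulse_energy_nJ
  # R^2 * 4*pi * P_true (uN/um^2) recovers F0 to machine precision
  expect_equal(obs$radius_um^2 * 4 * pi * 3.71 / 1000, f0, tolerance = 1e-12)

  # doubling the pressure shrinks every radius by sqrt(2)
  obs2 <- gen_counterbalance_set(2 * 3.71, seq(10, 60, 5), cal, noise_cv = 0,
                                 seed = 1)
  expect_equal(obs2$radius_um, obs$radius_um / sqrt(2), tolerance = 1e-12)

  expect_identical(gen_counterbalance_set(2, seed = 9, noise_cv = 0.1),
                   gen_counterbalance_set(2, seed = 9, noise_cv = 0.1))
  expect_error(gen_counterbalance_set(3.71, noise_cv = -0.1),
               class = "ringforce_invalid_input")
  expect_error(gen_counterbalance_set(-1), class = "ringforce_invalid_input")
})

test_that("extrusion cohorts encode the treatment delay", {
  exact <- gen_extrusion_cohort(5, mean_completion_s = 300, sd_s = 0,
                                delay_s = 100, seed = 1)
  means <- tapply(exact$completion_time_s, exact$condition, mean)
  expect_equal(unname(means[["Y27632"]] - means[["control"]]), 100)

  expect_identical(gen_extrusion_cohort(10, seed = 4),
                   gen_extrusion_cohort(10, seed = 4))
  expect_error(gen_extrusion_cohort(1), class = "ringforce_invalid_input")
  expect_error(gen_extrusion_cohort(5, sd_s = -1),
               class = "ringforce_invalid_input")
})

test_that("rendered movies are reproducible and contract after formation", {
  spec <- small_movie_spec()
  m1 <- gen_ring_movie(spec)
  m2 <- gen_ring_movie(spec)
  expect_identical(m1$frames, m2$frames)

  # noiseless, unloaded: ground-truth area strictly non-increasing once formed
  r <- m1$ground_truth$ring_radius_by_frame_um
  formed <- r > 0
  expect_true(all(diff(r[formed]) <= 0))
  # frames before formation are pure background
  expect_true(all(m1$frames[[1]] == m1$frames[[1]][1, 1]))
})

test_that("a ring too large for the field is rejected", {
  spec <- small_movie_spec(initial_radius_um = 11)
  expect_error(gen_ring_movie(spec), class = "ringforce_invalid_input")
})

test_that("movie loading windows are validated against the kinetic phase", {
  expect_error(
    small_movie_spec(loading_window = list(start_s = 5, pulse_energy_nJ = 40,
                                           end_s = 30)),
    class = "ringforce_invalid_input")
  expect_error(ring_movie_spec(frames = 1), class = "ringforce_invalid_input")
  expect_error(ring_movie_spec(formation_onset_s = 200,
                               completion_time_s = 100),
               class = "ringforce_invalid_input")
})

test_that("loaded movies plateau at the balance radius implied by the pressure", {
  spec <- small_movie_spec(
    loading_window = list(start_s = 25, pulse_energy_nJ = 60, end_s = 55),
    pressure_kPa = 3.71)
  mv <- gen_ring_movie(spec)
  # balance radius from the inverse slope-pressure conversion
  a <- 1000 / (4 * pi * 3.71)               # um^2/uN
  f0 <- 0.02 * 60
  expect_equal(mv$ground_truth$balance_radius_um, sqrt(a * f0),
               tolerance = 1e-12)
  # render + re-measure: the late-plateau frames sit at that radius (< 1 px)
  tr <- trace_ring(mv)
  late <- tr$time_s >= 45 & tr$time_s <= 55
  expect_lt(max(abs(tr$radius_um[late] - sqrt(a * f0))) / spec$pixel_size_um,
            1)
})

test_that("movie and table artifacts round-trip through their file formats", {
  tmp <- withr::local_tempdir()
  spec <- small_movie_spec(frames = 12L)
  mv <- gen_ring_movie(spec)
  p <- file.path(tmp, "movie.tif")
  write_ring_movie(mv, p)
  back <- read_ring_movie(p)
  expect_identical(back$frames, mv$frames)
  expect_equal(back$pixel_size_um, mv$pixel_size_um)
  expect_equal(back$times_s, mv$times_s)

  tab <- gen_calibration_table(8, seed = 2)
  pc <- file.path(tmp, "calib.csv")
  write_calibration_table(tab, pc)
  expect_equal(read_calibration_table(pc), tab, tolerance = 1e-12)

  cohort <- gen_extrusion_cohort(4, seed = 3)
  pk <- file.path(tmp, "cohort.csv")
  write_cohort_table(cohort, pk)
  expect_equal(read_cohort_table(pk), cohort, tolerance = 1e-12)

  obs <- gen_counterbalance_set(3.71, seed = 5)
  po <- file.path(tmp, "obs.csv")
  write_counterbalance_table(obs, po)
  expect_equal(read_counterbalance_table(po), obs, tolerance = 1e-12)
})
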