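test_that("effective radius is the circular-equivalent inverse of area", {
  expect_equal(effective_radius(pi), 1)
  expect_equal(effective_radius(0), 0)
  expect_equal(effective_radius(100 * pi), 10)
  r <- seq(0, 50, by = 0.7)
  expect_equal(effective_radius(pi * r^2), r, tolerance = 1e-12)
  expect_error(effective_radius(-1), class = "ringforce_invalid_input")
})

test_that("segmentation recovers annulus radii across the working range", {
  for (r in c(5, 8, 12, 20, 30, 40)) {
    noiseless <- segment_ring(render_annulus(r), pixel_size_um = 1)
    expect_equal(noiseless$flag, "ok")
    expect_lt(abs(noiseless$radius_um - r), 0.5)
    expect_equal(noiseless$area_um2, pi * noiseless$radius_um^2,
                 tolerance = 1e-12)

    noisy <- segment_ring(render_annulus(r, gaussian_sd = 100, seed = r),
                          pixel_size_um = 1)
    expect_equal(noisy$flag, "ok")
    expect_lt(abs(noisy$radius_um - r), 1)
  }
})

test_that("segmentation scales areas by the pixel size", {
  s <- segment_ring(render_annulus(20), pixel_size_um = 0.124)
  expect_equal(s$radius_um / 0.124, 20, tolerance = 0.5)
  expect_equal(s$area_um2, pi * s$radius_um^2, tolerance = 1e-12)
})

test_that("frames without ring structure are flagged, not measured", {
  expect_equal(segment_ring(matrix(100, 64, 64), 1)$flag, "no_ring")
  set.seed(11)
  blank <- matrix(rnorm(64 * 64, 100, 50), 64)
  s <- segment_ring(blank, 1)
  expect_true(s$flag %in% c("no_ring", "low_contrast"))
  expect_true(is.na(s$area_um2))
})

test_that("segmentation rejects invalid frames", {
  expect_error(segment_ring(array(1, c(4, 4, 2)), 1),
               class = "ringforce_invalid_input")
  expect_error(segment_ring(matrix(numeric(0), 0, 0), 1),
               class = "ringforce_invalid_input")
  expect_error(segment_ring(matrix(c(1, NA), 2, 2), 1),
               class = "ringforce_invalid_input")
  expect_error(segment_ring(render_annulus(10), pixel_size_um = 0),
               class = "ringforce_invalid_input")
})

test_that("tracing a noiseless movie recovers the ground-truth trajectory", {
  mv <- gen_ring_movie(small_movie_spec())
  tr <- trace_ring(mv)
  gt <- mv$ground_truth$ring_radius_by_frame_um
  formed <- gt > 0
  expect_true(all(tr$flag[formed] == "ok"))
  expect_true(all(tr$flag[!formed] == "no_ring"))
  expect_true(all(is.na(tr$area_um2[!formed])))
  err_px <- abs(tr$radius_um[formed] - gt[formed]) / mv$pixel_size_um
  expect_lt(max(err_px), 0.5)
})

test_that("tracing is constant on a repeated frame and validates shapes", {
  frame <- render_annulus(20)
  tr <- trace_ring(rep(list(frame), 10), pixel_size_um = 1,
                   frame_interval_s = 1)
  expect_equal(length(unique(tr$radius_um)), 1L)
  expect_error(
    trace_ring(list(frame, frame[1:64, ]), pixel_size_um = 1,
               frame_interval_s = 1),
    class = "ringforce_invalid_input")
  expect_error(trace_ring(list(frame), pixel_size_um = 1, frame_interval_s = 1),
               class = "ringforce_invalid_input")
})

test_that("event detection finds formation and completion on clean kinetics", {
  spec <- small_movie_spec(frames = 100L)  # movie outlives closure
  mv <- gen_ring_movie(spec)
  tr <- trace_ring(mv)
  ev <- detect_events(tr)
  expect_equal(ev$formation_s, 10, tolerance = 5)
  expect_null(ev$plateau)   # monotone contraction, no schedule given
  # closure threshold is 5% of peak area => radius sqrt(0.05)*r0, before 100 s
  expect_false(is.na(ev$completion_s))
  expect_lt(abs(ev$completion_s - (10 + 0.95 * 90)), 5)
})

test_that("noise moves detected events by at most two frame intervals", {
  base <- gen_ring_movie(small_movie_spec(frames = 100L))
  noisy <- gen_ring_movie(small_movie_spec(
    frames = 100L, noise = list(gaussian_sd = 100, poisson_scale = 1)))
  ev0 <- detect_events(trace_ring(base))
  ev1 <- detect_events(trace_ring(noisy))
  dt <- base$frame_interval_s
  expect_lte(abs(ev1$formation_s - ev0$formation_s), 2 * dt)
  expect_lte(abs(ev1$completion_s - ev0$completion_s), 2 * dt)
})

test_that("the counter-balanced plateau is detected at the balance radius", {
  spec <- small_movie_spec(
    loading_window = list(start_s = 25, pulse_energy_nJ = 60, end_s = 55),
    pressure_kPa = 3.71,
    noise = list(gaussian_sd = 100, poisson_scale = 1))
  mv <- gen_ring_movie(spec)
  ev <- detect_events(trace_ring(mv), loading_schedule = c(25, 55))
  expect_false(is.null(ev$plateau))
  err_px <- abs(ev$plateau$radius_um - mv$ground_truth$balance_radius_um) /
    spec$pixel_size_um
  expect_lt(err_px, 1)
  expect_gte(ev$plateau$start_s, 25)
  expect_lte(ev$plateau$end_s, 55)
})

test_that("event detection refuses traces without enough valid frames", {
  tr <- structure(
    data.frame(time_s = 1:6, area_um2 = c(NA, NA, 1, 1, NA, NA),
               radius_um = NA, flag = c("no_ring", "no_ring", "ok", "ok",
                                        "no_ring", "no_ring")),
    class = c("ring_trace", "data.frame"))
  expect_error(detect_events(tr), class = "ringforce_event_error")
})

test_that("ring traces round-trip through CSV", {
  mv <- gen_ring_movie(small_movie_spec(frames = 12L))
  tr <- trace_ring(mv)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_ring_trace(tr, tmp)
  back <- read_ring_trace(tmp, pixel_size_um = mv$pixel_size_um)
  expect_equal(back$area_um2, tr$area_um2, tolerance = 1e-9)
  expect_equal(back$flag, tr$flag)
})
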