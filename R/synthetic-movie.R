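#' Specify a synthetic actomyosin-ring time-lapse movie
#'
#' Collects the imaging geometry, ring kinetics, optional impulsive-force
#' loading window and noise model for [gen_ring_movie()].  The kinetic
#' scenario follows the in vivo sequence: no ring before `formation_onset_s`
#' (about 120 s after the cell-death-inducing irradiation), then contraction
#' of the enclosed area towards closure at `completion_time_s`; when a
#' loading window is present, the ring relaxes towards the counter-balanced
#' radius implied by the ground-truth pressure and the loaded pulse energy,
#' plateaus there, and resumes contraction once loading stops.
#'
#' @param pixel_size_um um per pixel, default 0.124.
#' @param frame_interval_s seconds between frames, default 1.
#' @param frames number of frames (>= 2), default 300.
#' @param field_px square field size in pixels, default 512.
#' @param induction_time_s time of the cell-death-inducing pulse; frame 1 is
#'   acquired at this time (default 0).
#' @param formation_onset_s ring formation time (s), default 120.
#' @param completion_time_s unloaded closure time (s), default 420.
#' @param initial_radius_um ring radius at formation (um), default 5.
#' @param loading_window `NULL`, or a list with `start_s`, `pulse_energy_nJ`
#'   and either `end_s` or `pulse_count` (default 50) with `pulse_interval_s`
#'   (default 1); the window must lie inside
#'   `[formation_onset_s, completion_time_s]`.
#' @param pressure_kPa ground-truth contractile pressure (kPa) used to place
#'   the counter-balanced plateau, default 3.71.
#' @param calib `calibration_model` converting pulse energy to force.
#' @param contraction one of `"linear"` (area decreases linearly in time) or
#'   `"exponential"` (area decays exponentially, reaching 5% of its initial
#'   value at `completion_time_s`).
#' @param relax_tau_s time constant (s) of the relaxation towards the balance
#'   radius during loading, default 5.
#' @param ring_sigma_um radial Gaussian half-thickness of the rendered ring
#'   (um), default 0.3.
#' @param amplitude peak ring intensity above background (16-bit counts),
#'   default 1000.
#' @param background background intensity, default 100.
#' @param noise list with `gaussian_sd` (read noise, counts; default 100,
#'   i.e. SNR 10 at the default amplitude) and `poisson_scale`
#'   (photons per count for shot noise; 0 disables, default 1).
#' @param seed integer seed.
#' @return a `ring_movie_spec` list.
#' @export
ring_movie_spec <- function(pixel_size_um = 0.124, frame_interval_s = 1,
                            frames = 300L, field_px = 512L,
                            induction_time_s = 0, formation_onset_s = 120,
                            completion_time_s = 420, initial_radius_um = 5,
                            loading_window = NULL, pressure_kPa = 3.71,
                            calib = calibration_model(0.02),
                            contraction = c("linear", "exponential"),
                            relax_tau_s = 5, ring_sigma_um = 0.3,
                            amplitude = 1000, background = 100,
                            noise = list(gaussian_sd = 100, poisson_scale = 1),
                            seed = 1L) {
  contraction <- match.arg(contraction)
  if (frames < 2L) abort_invalid("need at least 2 frames")
  if (pixel_size_um <= 0) abort_invalid("pixel size must be positive")
  if (formation_onset_s >= completion_time_s)
    abort_invalid("formation must precede completion")
  if (initial_radius_um <= 0) abort_invalid("initial radius must be positive")
  noise <- utils::modifyList(list(gaussian_sd = 100, poisson_scale = 1), noise)
  if (noise$gaussian_sd < 0 || noise$poisson_scale < 0)
    abort_invalid("noise parameters must be non-negative")

  if (!is.null(loading_window)) {
    lw <- utils::modifyList(list(pulse_count = 50L, pulse_interval_s = 1),
                            loading_window)
    if (is.null(lw$start_s) || is.null(lw$pulse_energy_nJ))
      abort_invalid("loading_window needs start_s and pulse_energy_nJ")
    if (is.null(lw$end_s)) lw$end_s <- lw$start_s + lw$pulse_count * lw$pulse_interval_s
    if (lw$start_s < formation_onset_s || lw$end_s > completion_time_s ||
        lw$start_s >= lw$end_s)
      abort_invalid("loading window must lie inside [formation, completion]")
    loading_window <- lw
  }
  spec <- list(pixel_size_um = pixel_size_um,
               frame_interval_s = frame_interval_s,
               frames = as.integer(frames), field_px = as.integer(field_px),
               induction_time_s = induction_time_s,
               formation_onset_s = formation_onset_s,
               completion_time_s = completion_time_s,
               initial_radius_um = initial_radius_um,
               loading_window = loading_window,
               pressure_kPa = pressure_kPa, calib = calib,
               contraction = contraction, relax_tau_s = relax_tau_s,
               ring_sigma_um = ring_sigma_um, amplitude = amplitude,
               background = background, noise = noise,
               seed = as.integer(seed))
  class(spec) <- "ring_movie_spec"
  spec
}

# ground-truth ring radius (um) at each frame time, plus event times;
# radius 0 encodes "no ring yet" / "closed"
ring_trajectory <- function(spec) {
  times <- spec$induction_time_s +
    (seq_len(spec$frames) - 1L) * spec$frame_interval_s
  tf <- spec$formation_onset_s
  tc <- spec$completion_time_s
  A0 <- pi * spec$initial_radius_um^2
  lw <- spec$loading_window

  area_unloaded <- function(dt) {  # dt = time since formation (>= 0)
    if (spec$contraction == "linear") {
      rate <- A0 / (tc - tf)
      pmax(A0 - rate * dt, 0)
    } else {
      k <- log(20) / (tc - tf)    # 5% of A0 left at completion
      A0 * exp(-k * dt)
    }
  }
  # area consumed per unit time at area A (to resume contraction post-load)
  rate_at <- function(A) {
    if (spec$contraction == "linear") A0 / (tc - tf) else log(20) / (tc - tf) * A
  }

  radius <- numeric(spec$frames)
  balance_radius <- NA_real_
  completion_actual <- tc
  if (is.null(lw)) {
    after <- times >= tf
    radius[after] <- sqrt(area_unloaded(times[after] - tf) / pi)
    if (spec$contraction == "exponential") completion_actual <- tc
  } else {
    F0 <- as.numeric(suppressWarnings(
      force_from_energy(spec$calib, lw$pulse_energy_nJ)))
    balance_radius <- sqrt(F0 / (4 * pi * spec$pressure_kPa / .kpa_per_uN_um2))
    r_enter <- sqrt(area_unloaded(lw$start_s - tf) / pi)
    r_exit <- balance_radius + (r_enter - balance_radius) *
      exp(-(lw$end_s - lw$start_s) / spec$relax_tau_s)
    A_exit <- pi * r_exit^2
    for (i in seq_along(times)) {
      t <- times[i]
      radius[i] <- if (t < tf) 0
      else if (t < lw$start_s) sqrt(area_unloaded(t - tf) / pi)
      else if (t <= lw$end_s)
        balance_radius + (r_enter - balance_radius) *
          exp(-(t - lw$start_s) / spec$relax_tau_s)
      else {
        if (spec$contraction == "linear")
          sqrt(pmax(A_exit - rate_at(A_exit) * (t - lw$end_s), 0) / pi)
        else
          sqrt(A_exit * exp(-log(20) / (tc - tf) * (t - lw$end_s)) / pi)
      }
    }
    completion_actual <- if (spec$contraction == "linear")
      lw$end_s + A_exit / rate_at(A_exit) else
      lw$end_s + (tc - tf)  # time to decay to 5% of A_exit
  }
  list(times_s = times, radius_um = radius,
       balance_radius_um = balance_radius,
       event_times_s = list(
         formation = tf,
         loading_start = if (is.null(lw)) NA_real_ else lw$start_s,
         loading_end = if (is.null(lw)) NA_real_ else lw$end_s,
         completion = completion_actual))
}

#' Render a synthetic ring movie with ground truth
#'
#' Renders each frame as a bright annulus with a radial Gaussian intensity
#' profile centred in the field, the centreline radius following the
#' ground-truth trajectory implied by the spec (see [ring_movie_spec()]).
#' Per-frame noise is Poisson shot noise on the signal plus additive Gaussian
#' read noise; frames are quantised to 16-bit counts.
#'
#' @param spec a `ring_movie_spec`.
#' @return a `ring_movie`: list with `frames` (list of integer matrices),
#'   `times_s`, `pixel_size_um`, `frame_interval_s`, `spec` and
#'   `ground_truth` (ground-truth pressure, per-frame radii, balance radius
#'   and event times).
#' @export
gen_ring_movie <- function(spec) {
  if (!inherits(spec, "ring_movie_spec"))
    abort_invalid("spec must be a ring_movie_spec")
  traj <- ring_trajectory(spec)
  half_um <- spec$field_px / 2 * spec$pixel_size_um
  if (max(traj$radius_um) + 4 * spec$ring_sigma_um >= half_um)
    abort_invalid("ring radius exceeds the field of view; enlarge field_px")

  ctr <- (spec$field_px + 1) / 2
  ax <- (seq_len(spec$field_px) - ctr) * spec$pixel_size_um
  dist_um <- sqrt(outer(ax^2, ax^2, "+"))  # distance of pixel centres, um

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  npx <- spec$field_px^2
  frames <- vector("list", spec$frames)
  for (i in seq_len(spec$frames)) {
    r <- traj$radius_um[i]
    ideal <- matrix(spec$background, spec$field_px, spec$field_px)
    if (r > 0)
      ideal <- ideal + spec$amplitude *
        exp(-((dist_um - r)^2) / (2 * spec$ring_sigma_um^2))
    img <- ideal
    if (spec$noise$poisson_scale > 0)
      img <- stats::rpois(npx, ideal * spec$noise$poisson_scale) /
        spec$noise$poisson_scale
    if (spec$noise$gaussian_sd > 0)
      img <- img + rnorm(npx, 0, spec$noise$gaussian_sd)
    img <- matrix(pmin(pmax(round(img), 0), 65535L), spec$field_px)
    storage.mode(img) <- "integer"
    frames[[i]] <- img
  }
  structure(
    list(frames = frames, times_s = traj$times_s,
         pixel_size_um = spec$pixel_size_um,
         frame_interval_s = spec$frame_interval_s,
         spec = spec,
         ground_truth = list(
           pressure_kPa = spec$pressure_kPa,
           ring_radius_by_frame_um = traj$radius_um,
           balance_radius_um = traj$balance_radius_um,
           event_times_s = traj$event_times_s)),
    class = "ring_movie")
}

#' @export
print.ring_movie <- function(x, ...) {
  cat(sprintf("Synthetic ring movie: %d frames of %dx%d px (%.3f um/px, %g s/frame)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size_um, x$frame_interval_s))
  ev <- x$ground_truth$event_times_s
  cat(sprintf("  ground truth: formation %g s, completion %g s, P = %g kPa\n",
              ev$formation, ev$completion, x$ground_truth$pressure_kPa))
  invisible(x)
}

#' Read / write ring movies as multi-page TIFF
#'
#' One 16-bit grayscale page per time point; pixel size and frame interval
#' travel in a JSON sidecar (written next to the TIFF as `<stem>.json`)
#' rather than in TIFF tag dialects.
#'
#' @param movie a `ring_movie` (or any list of equally sized integer
#'   matrices plus metadata fields).
#' @param path TIFF file path.
#' @return `read_ring_movie`: a list with `frames`, `times_s`,
#'   `pixel_size_um`, `frame_interval_s`.
#' @name movie_io
#' @export
write_ring_movie <- function(movie, path) {
  pages <- lapply(movie$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = movie$pixel_size_um,
               frame_interval_s = movie$frame_interval_s,
               times_s = movie$times_s)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname movie_io
#' @param pixel_size_um,frame_interval_s metadata overrides; when `NULL`
#'   they are taken from the JSON sidecar.
#' @export
read_ring_movie <- function(path, pixel_size_um = NULL,
                            frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  meta <- list()
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    abort_invalid("pixel size / frame interval not supplied and no sidecar found")
  times <- meta$times_s %||% ((seq_along(frames) - 1) * frame_interval_s)
  list(frames = frames, times_s = times, pixel_size_um = pixel_size_um,
       frame_interval_s = frame_interval_s)
}

#' Write ground truth as JSON
#'
#' @param movie a `ring_movie`.
#' @param path JSON path.
#' @export
write_ground_truth <- function(movie, path) {
  jsonlite::write_json(movie$ground_truth, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
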