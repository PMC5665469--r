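#' Run the full measurement-to-comparison pipeline
#'
#' Orchestrates the stages on configured inputs: `measure` (time-lapse TIFF
#' -> ring trace -> events), `calibrate` (calibration CSV -> energy/force
#' model), `infer` (counter-balance CSV + model -> balance fit -> pressure
#' with bootstrap CI, per condition) and `compare` (per-condition table
#' against a baseline).  Stages whose inputs are absent from the config are
#' skipped; any stage error is re-raised with the stage name.  Every run
#' writes a manifest (inputs, config hash, seed, package version) so a rerun
#' with the same config and seed reproduces the same artifacts.
#'
#' @param config a named list (or path to a JSON file holding one) with any
#'   of: `out_dir`; `calibration_table` (CSV path); `movie` (TIFF path),
#'   `pixel_size_um`, `frame_interval_s`, `loading` (`c(start_s, end_s)`);
#'   `observations` (counter-balance CSV, may hold several conditions);
#'   `cohort` (completion-time CSV); `through_origin`; `geometry_factor`;
#'   `n_boot`; `seed`; `baseline`.
#' @return a `pipeline_report` list with elements `calibration`, `trace`,
#'   `events`, `pressures` (per condition), `comparison` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(out_dir = NULL, through_origin = TRUE, geometry_factor = 4 * pi,
         n_boot = 2000L, seed = 1L, baseline = "control"),
    config)
  report <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  calib <- NULL
  if (!is.null(cfg$calibration_table)) {
    calib <- stage("calibrate", {
      if (!file.exists(cfg$calibration_table))
        abort_invalid("calibration table not found: ", cfg$calibration_table)
      fit_calibration(read_calibration_table(cfg$calibration_table),
                      through_origin = cfg$through_origin)
    })
    report$calibration <- calib
  }

  if (!is.null(cfg$movie)) {
    report$trace <- stage("measure", {
      if (!file.exists(cfg$movie)) abort_invalid("movie not found: ", cfg$movie)
      mv <- read_ring_movie(cfg$movie, cfg$pixel_size_um, cfg$frame_interval_s)
      trace_ring(mv)
    })
    report$events <- stage("measure", {
      detect_events(report$trace, loading_schedule = cfg$loading)
    })
  }

  if (!is.null(cfg$observations)) {
    report$pressures <- stage("infer", {
      if (is.null(calib)) abort_invalid("inference needs a calibration table")
      if (!file.exists(cfg$observations))
        abort_invalid("observations not found: ", cfg$observations)
      obs <- read_counterbalance_table(cfg$observations)
      out <- list()
      for (cond in unique(obs$condition)) {
        sub <- obs[obs$condition == cond, , drop = FALSE]
        fit <- fit_balance_line(sub, calib, cfg$through_origin)
        est <- bootstrap_pressure(sub, calib, n_boot = cfg$n_boot,
                                  seed = cfg$seed,
                                  through_origin = cfg$through_origin,
                                  geometry_factor = cfg$geometry_factor)
        out[[cond]] <- list(fit = fit, pressure = est)
      }
      out
    })
  }

  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    cohort <- stage("compare", {
      if (!file.exists(cfg$cohort)) abort_invalid("cohort not found: ", cfg$cohort)
      read_cohort_table(cfg$cohort)
    })
  }
  if (!is.null(report$pressures) || !is.null(cohort)) {
    report$comparison <- stage("compare", {
      conds <- union(names(report$pressures), unique(cohort$condition))
      results <- lapply(conds, function(cond) {
        entry <- list()
        if (!is.null(report$pressures[[cond]]))
          entry$pressure <- report$pressures[[cond]]$pressure
        if (!is.null(cohort)) {
          v <- cohort$completion_time_s[cohort$condition == cond]
          if (length(v) >= 2L) entry$times <- group_sample(cond, v, "s")
        }
        entry
      })
      names(results) <- conds
      if (!cfg$baseline %in% conds)
        abort_invalid("baseline '", cfg$baseline, "' absent from results")
      compare_conditions(results, baseline = cfg$baseline)
    })
  }

  report$manifest <- pipeline_manifest(cfg)
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir)
  report
}

pipeline_manifest <- function(cfg) {
  flat <- cfg[order(names(cfg))]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  list(config = flat,
       config_md5 = unname(tools::md5sum(tmp)),
       seed = cfg$seed,
       package = "ringforce",
       version = as.character(utils::packageVersion("ringforce")))
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$calibration))
    write_calibration_model(report$calibration,
                            file.path(out_dir, "calibration_model.json"))
  if (!is.null(report$trace))
    write_ring_trace(report$trace, file.path(out_dir, "ring_trace.csv"))
  if (!is.null(report$events))
    write_event_times(report$events, file.path(out_dir, "event_times.json"))
  if (!is.null(report$pressures))
    for (cond in names(report$pressures))
      write_pressure_result(report$pressures[[cond]]$pressure,
                            file.path(out_dir, paste0("pressure_", cond, ".json")),
                            fit = report$pressures[[cond]]$fit)
  if (!is.null(report$comparison))
    write_comparison(report$comparison, file.path(out_dir, "comparison"))
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("ringforce pipeline report\n")
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$events)) print(x$events)
  if (!is.null(x$pressures))
    for (cond in names(x$pressures)) print(x$pressures[[cond]]$pressure)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Simulation-backed rehearsal of the full counter-balance experiment
#'
#' Generates every input the in vivo workflow would produce — an AFM-style
#' calibration table, counter-balance observation sets for control and two
#' inhibitor conditions with ground-truth pressures 3.71, 2.58 and 2.40 kPa,
#' extrusion-timing cohorts with a 100 s treatment delay, and (optionally)
#' one loaded ring movie — then runs the full pipeline and reports recovered
#' versus ground-truth values per condition.
#'
#' @param seed integer master seed; condition-level seeds are derived from
#'   it, so two seeds give different noise realisations of the same ground
#'   truth.
#' @param out_dir optional directory for all written artifacts.
#' @param n_obs counter-balance observations per condition, default 30.
#' @param noise_cv radius measurement CV, default 0.1.
#' @param n_boot bootstrap resamples, default 1000.
#' @param render_movie also render, re-measure and event-detect one loaded
#'   control movie (slower), default `TRUE`.
#' @param movie_frames frames in the rendered movie, default 260.
#' @param field_px movie field size, default 512.
#' @return a `demo_report` list with `truth_kPa`, `recovery` (data frame of
#'   truth vs estimate and relative error per condition), `pressures`,
#'   `comparison`, and when a movie was rendered `events` plus
#'   `plateau_radius_um` with its ground-truth counterpart.
#' @export
demo_paper_workflow <- function(seed = 42L, out_dir = NULL, n_obs = 30L,
                                noise_cv = 0.1, n_boot = 1000L,
                                render_movie = TRUE, movie_frames = 260L,
                                field_px = 512L) {
  seed <- as.integer(seed)
  truth <- c(control = 3.71, Y27632 = 2.58, blebbistatin = 2.40)

  calib_tab <- gen_calibration_table(n_points = 20, slope_uN_per_nJ = 0.02,
                                     noise_sd_uN = 0.05,
                                     energy_range_nJ = c(10, 60),
                                     seed = seed)
  calib <- fit_calibration(calib_tab)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  pressures <- list(); obs_all <- list()
  for (i in seq_along(truth)) {
    cond <- names(truth)[i]
    set.seed(seed + 100L * i)
    energies <- runif(n_obs, 10, 60)
    obs <- gen_counterbalance_set(truth[[cond]], energies_nJ = energies,
                                  calib = calib, noise_cv = noise_cv,
                                  n_reps = 1L, seed = seed + 100L * i + 1L,
                                  condition = cond)
    fit <- fit_balance_line(obs, calib)
    est <- bootstrap_pressure(obs, calib, n_boot = n_boot,
                              seed = seed + 100L * i + 2L)
    pressures[[cond]] <- list(fit = fit, pressure = est)
    obs_all[[cond]] <- obs
  }

  cohorts <- list()
  for (i in 2:3) {
    cond <- names(truth)[i]
    cohorts[[cond]] <- gen_extrusion_cohort(
      n_per_group = 10L, mean_completion_s = 300, sd_s = 20, delay_s = 100,
      seed = seed + 10L * i, treated_condition = cond)
  }
  cohort <- rbind(cohorts[[1]],
                  cohorts[[2]][cohorts[[2]]$condition != "control", ])

  results <- lapply(names(truth), function(cond) {
    entry <- list(pressure = pressures[[cond]]$pressure)
    v <- cohort$completion_time_s[cohort$condition == cond]
    if (length(v) >= 2L) entry$times <- group_sample(cond, v, "s")
    entry
  })
  names(results) <- names(truth)
  comparison <- compare_conditions(results, baseline = "control")

  recovery <- data.frame(
    condition = names(truth),
    truth_kPa = unname(truth),
    estimate_kPa = vapply(names(truth),
                          function(c) pressures[[c]]$pressure$pressure_kPa,
                          numeric(1)),
    row.names = NULL)
  recovery$relative_error <- (recovery$estimate_kPa - recovery$truth_kPa) /
    recovery$truth_kPa

  report <- list(truth_kPa = truth, calibration = calib,
                 pressures = pressures, observations = obs_all,
                 cohort = cohort, comparison = comparison,
                 recovery = recovery, seed = seed)

  if (render_movie) {
    spec <- ring_movie_spec(frames = movie_frames, field_px = field_px,
                            loading_window = list(start_s = 138,
                                                  pulse_energy_nJ = 60),
                            pressure_kPa = truth[["control"]],
                            calib = calibration_model(0.02),
                            seed = seed + 7L)
    movie <- gen_ring_movie(spec)
    trace <- trace_ring(movie)
    events <- detect_events(trace, loading_schedule = c(138, 188))
    report$trace <- trace
    report$events <- events
    report$plateau_radius_um <- if (!is.null(events$plateau))
      events$plateau$radius_um else NA_real_
    report$plateau_truth_um <- movie$ground_truth$balance_radius_um
    if (!is.null(events$plateau)) {
      f0 <- force_from_energy(calib, 60)
      report$plateau_pressure_kPa <- point_pressure(f0,
                                                    events$plateau$radius_um)
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_ring_movie(movie, file.path(out_dir, "control_movie.tif"))
      write_ground_truth(movie, file.path(out_dir, "control_movie_truth.json"))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calibration_table(calib_tab, file.path(out_dir, "calibration.csv"))
    write_calibration_model(calib, file.path(out_dir, "calibration_model.json"))
    write_counterbalance_table(do.call(rbind, obs_all),
                               file.path(out_dir, "counterbalance.csv"))
    write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
    for (cond in names(pressures))
      write_pressure_result(pressures[[cond]]$pressure,
                            file.path(out_dir, paste0("pressure_", cond, ".json")),
                            fit = pressures[[cond]]$fit)
    write_comparison(comparison, file.path(out_dir, "comparison"))
    write.csv(recovery, file.path(out_dir, "recovery.csv"), row.names = FALSE)
    if (!is.null(report$trace))
      write_ring_trace(report$trace, file.path(out_dir, "ring_trace.csv"))
    if (!is.null(report$events))
      write_event_times(report$events, file.path(out_dir, "event_times.json"))
  }
  class(report) <- "demo_report"
  report
}

#' @export
print.demo_report <- function(x, ...) {
  cat("Simulation-backed counter-balance workflow (seed ", x$seed, ")\n",
      sep = "")
  cat("\nPressure recovery (kPa):\n")
  print.data.frame(x$recovery, row.names = FALSE, digits = 4)
  if (!is.null(x$events)) {
    cat("\nControl movie events:\n")
    print(x$events)
    cat(sprintf("  plateau radius: %.3f um (ground truth %.3f um)\n",
                x$plateau_radius_um, x$plateau_truth_um))
  }
  cat("\n")
  print(x$comparison)
  invisible(x)
}
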