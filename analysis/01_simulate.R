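#!/usr/bin/env Rscript
# Stage 1 — generate every input the in vivo workflow would produce.
#
# The counter-balance experiment needs four kinds of raw data: an AFM-style
# calibration table (pulse energy L vs total impulsive force F0), one
# fluorescence time-lapse of a loaded actomyosin ring, counter-balance
# observation sets (L, stalled radius R) for control and two
# myosin-inhibited conditions, and extrusion-completion cohorts.  All are
# simulated here under known ground truths — contractile pressures of
# 3.71 (control), 2.58 (Y27632) and 2.40 kPa (blebbistatin), ring formation
# 120 s after the death-inducing pulse, and a 100 s completion delay under
# inhibition — so later stages can be scored against the truth.

suppressPackageStartupMessages(library(ringforce))
seed <- 42L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

truth <- c(control = 3.71, Y27632 = 2.58, blebbistatin = 2.40)

message("calibration table: 20 points, 0.02 uN/nJ through the origin, ",
        "sd 0.05 uN")
calib_tab <- gen_calibration_table(20, slope_uN_per_nJ = 0.02,
                                   noise_sd_uN = 0.05,
                                   energy_range_nJ = c(10, 60), seed = seed)
write_calibration_table(calib_tab, file.path(data_dir, "calibration.csv"))

message("counter-balance sets: 30 observations/condition, energies 10-60 nJ, ",
        "radius CV 10%")
cal_true <- calibration_model(0.02)
obs <- do.call(rbind, lapply(seq_along(truth), function(i) {
  set.seed(seed + 100L * i)
  energies <- runif(30, 10, 60)
  gen_counterbalance_set(truth[[i]], energies, cal_true, noise_cv = 0.1,
                         seed = seed + 100L * i + 1L,
                         condition = names(truth)[i])
}))
write_counterbalance_table(obs, file.path(data_dir, "counterbalance.csv"))

message("extrusion cohorts: n = 10/group, sd 20 s, inhibitor delay 100 s")
cohorts <- lapply(2:3, function(i)
  gen_extrusion_cohort(10L, mean_completion_s = 300, sd_s = 20, delay_s = 100,
                       seed = seed + 10L * i,
                       treated_condition = names(truth)[i]))
cohort <- rbind(cohorts[[1]],
                cohorts[[2]][cohorts[[2]]$condition != "control", ])
write_cohort_table(cohort, file.path(data_dir, "cohort.csv"))

message("loaded control movie: 260 frames at 1 s, 512x512 px, SNR 10, ",
        "60 nJ loading at 138-188 s")
spec <- ring_movie_spec(frames = 260L, field_px = 512L,
                        loading_window = list(start_s = 138,
                                              pulse_energy_nJ = 60),
                        pressure_kPa = truth[["control"]],
                        calib = cal_true, seed = seed + 7L)
movie <- gen_ring_movie(spec)
write_ring_movie(movie, file.path(data_dir, "control_movie.tif"))
write_ground_truth(movie, file.path(data_dir, "control_movie_truth.json"))

message("ground truth: balance radius ",
        round(movie$ground_truth$balance_radius_um, 3), " um; inputs in ",
        data_dir)
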