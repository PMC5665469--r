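#!/usr/bin/env Rscript
# Stage 2 — measure the ring trajectory and detect its events.
#
# Re-measures the rendered time-lapse frame by frame (segmentation ->
# enclosed area in um^2 -> effective radius), then detects formation onset,
# the counter-balanced plateau inside the 138-188 s loading schedule, and
# completion if it falls inside the movie.  The plateau radius is the
# experiment's key readout: it should sit at the radius where the impulsive
# load and ring contraction stall each other.

suppressPackageStartupMessages(library(ringforce))
data_dir <- "results/data"
out_dir <- "results"

movie <- read_ring_movie(file.path(data_dir, "control_movie.tif"))
trace <- trace_ring(movie)
write_ring_trace(trace, file.path(out_dir, "ring_trace.csv"))

events <- detect_events(trace, loading_schedule = c(138, 188))
write_event_times(events, file.path(out_dir, "event_times.json"))
print(events)

truth <- jsonlite::read_json(file.path(data_dir, "control_movie_truth.json"),
                             simplifyVector = TRUE)
message(sprintf("formation: detected %g s vs truth %g s",
                events$formation_s, truth$event_times_s$formation))
if (!is.null(events$plateau))
  message(sprintf("plateau radius: %.3f um vs ground-truth balance %.3f um",
                  events$plateau$radius_um, truth$balance_radius_um))
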