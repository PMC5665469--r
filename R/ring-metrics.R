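#' Circular-equivalent radius of a ring area
#'
#' Links the two readouts used for the actomyosin ring: its size in um^2 and
#' its radius in um, via `r = sqrt(area / pi)`.
#'
#' @param area_um2 non-negative area(s) in um^2.
#' @return radius (um).
#' @export
effective_radius <- function(area_um2) {
  if (any(!is.na(area_um2) & area_um2 < 0))
    abort_invalid("area must be non-negative")
  sqrt(area_um2 / pi)
}

#' Segment the actomyosin ring in a single frame
#'
#' Operator chain: Gaussian smoothing (sigma 1 px), Otsu threshold,
#' morphological closing (3x3), largest connected component, then gates on
#' minimum size, circularity of the filled component (4*pi*A/P^2 >= 0.6) and
#' foreground/background contrast.  The ring radius is the centreline radius
#' of the bright band, estimated as the weighted mean distance of band
#' pixels from the band centroid with weights (intensity - threshold) /
#' distance; the 1/distance factor cancels the growth of pixel count with
#' radius, so the estimate is unbiased for any radially symmetric band
#' profile.  Area is reported as the enclosed disk pi * r^2.
#'
#' @param frame 2D numeric matrix of pixel intensities.
#' @param pixel_size_um um per pixel, positive.
#' @param smooth_sigma_px Gaussian smoothing sigma (px), default 1.
#' @param min_circularity circularity gate on the filled component,
#'   default 0.6.
#' @param min_area_px minimum band size in pixels, default 50.
#' @param min_contrast minimum (foreground mean - background median) /
#'   background mad, default 3.
#' @return list with `area_um2` (NA when no ring), `radius_um`, `flag`
#'   (one of `"ok"`, `"no_ring"`, `"low_contrast"`) and `center_px`.
#' @export
segment_ring <- function(frame, pixel_size_um, smooth_sigma_px = 1,
                         min_circularity = 0.6, min_area_px = 50,
                         min_contrast = 3) {
  if (!is.matrix(frame) || length(frame) == 0L)
    abort_invalid("frame must be a non-empty 2D matrix")
  if (!all(is.finite(frame))) abort_invalid("frame contains non-finite values")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    abort_invalid("pixel size must be positive")

  none <- list(area_um2 = NA_real_, radius_um = NA_real_, flag = "no_ring",
               center_px = c(NA_real_, NA_real_))
  rng <- range(frame)
  if (diff(rng) == 0) return(none)

  norm <- (frame - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(norm), sigma = smooth_sigma_px)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(mask)
  nobj <- max(lab)
  if (nobj < 1) return(none)

  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0], nbins = nobj)
  id <- which.max(sizes)
  if (sizes[id] < min_area_px) return(none)
  band <- imageData(lab) == id

  # circularity of the filled component
  filled <- EBImage::fillHull(EBImage::Image(band * 1))
  shp <- EBImage::computeFeatures.shape(EBImage::bwlabel(filled))
  circ <- 4 * pi * shp[1, "s.area"] / shp[1, "s.perimeter"]^2
  if (!is.finite(circ) || circ < min_circularity) return(none)

  # contrast gate against the (robust) background level
  bg_med <- median(frame[!band])
  bg_mad <- stats::mad(frame[!band])
  fg_mean <- mean(frame[band])
  if (bg_mad > 0 && (fg_mean - bg_med) / bg_mad < min_contrast) {
    none$flag <- "low_contrast"
    return(none)
  }

  idx <- which(band, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  d <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
  w <- (frame[band] - (rng[1] + thr * diff(rng))) / pmax(d, 0.5)
  w <- pmax(w, 0)
  if (sum(w) <= 0) return(none)
  r_px <- sum(w * d) / sum(w)
  r_um <- r_px * pixel_size_um
  list(area_um2 = pi * r_um^2, radius_um = r_um, flag = "ok",
       center_px = c(cx, cy))
}

imageData <- function(x) EBImage::imageData(x)

#' Measure the ring trajectory of an image stack
#'
#' Runs [segment_ring()] on every frame and assembles a `ring_trace`:
#' a data frame with one row per frame (`time_s`, `area_um2`, `radius_um`,
#' `flag`), where frames without a detectable ring carry `NA` area.
#'
#' @param stack a `ring_movie`, a list of equally sized matrices, or a 3D
#'   array (row, col, frame).
#' @param pixel_size_um um per pixel (taken from the movie if omitted).
#' @param frame_interval_s seconds per frame (taken from the movie if
#'   omitted).
#' @param times_s optional explicit frame times (s).
#' @param ... gate parameters passed to [segment_ring()].
#' @return a `ring_trace` data frame with attributes `pixel_size_um` and
#'   `frame_interval_s`.
#' @export
trace_ring <- function(stack, pixel_size_um = NULL, frame_interval_s = NULL,
                       times_s = NULL, ...) {
  if (inherits(stack, "ring_movie") ||
      (is.list(stack) && !is.null(stack$frames))) {
    pixel_size_um <- pixel_size_um %||% stack$pixel_size_um
    frame_interval_s <- frame_interval_s %||% stack$frame_interval_s
    times_s <- times_s %||% stack$times_s
    stack <- stack$frames
  }
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) < 2L)
    abort_invalid("need an image stack with at least 2 frames")
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_invalid("inconsistent frame shapes in stack")
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    abort_invalid("pixel_size_um and frame_interval_s are required")
  times_s <- times_s %||% ((seq_along(stack) - 1) * frame_interval_s)
  if (any(diff(times_s) <= 0)) abort_invalid("times must be strictly increasing")

  segs <- lapply(stack, segment_ring, pixel_size_um = pixel_size_um, ...)
  trace <- data.frame(
    time_s = times_s,
    area_um2 = vapply(segs, function(s) s$area_um2, numeric(1)),
    radius_um = vapply(segs, function(s) s$radius_um, numeric(1)),
    flag = vapply(segs, function(s) s$flag, character(1)))
  attr(trace, "pixel_size_um") <- pixel_size_um
  attr(trace, "frame_interval_s") <- frame_interval_s
  class(trace) <- c("ring_trace", "data.frame")
  trace
}

#' Detect formation, counter-balance plateau and completion events
#'
#' Formation is the first time a ring is found in `k_formation` consecutive
#' frames.  Completion is the first time the enclosed area falls below
#' `closure_fraction` of its peak, or the ring disappears after sustained
#' contraction.  When a loading schedule is supplied, the counter-balanced
#' plateau is the maximal sub-interval of the schedule over which the local
#' area-change rate |dA/dt| (slope of a windowed linear fit) stays below
#' `stall_fraction` of the pre-loading contraction rate; the counter-balanced
#' radius R is the mean effective radius over that interval.
#'
#' @param trace a `ring_trace` from [trace_ring()].
#' @param loading_schedule `NULL` or `c(start_s, end_s)` of impulsive-force
#'   loading.
#' @param k_formation consecutive ring detections required, default 3.
#' @param closure_fraction completion threshold as a fraction of peak area,
#'   default 0.05.
#' @param stall_fraction stall threshold as a fraction of the pre-loading
#'   contraction rate, default 0.2.
#' @param slope_window_s window (s) of the local linear fits used for
#'   |dA/dt|, default 15.
#' @return an `event_times` list: `formation_s`, `completion_s` (either may
#'   be `NA`), `plateau` (`NULL` or list with `start_s`, `end_s`,
#'   `radius_um`).
#' @export
detect_events <- function(trace, loading_schedule = NULL, k_formation = 3L,
                          closure_fraction = 0.05, stall_fraction = 0.2,
                          slope_window_s = 15) {
  ok <- trace$flag == "ok" & is.finite(trace$area_um2)
  if (sum(ok) < 5L)
    abort_event("event detection failed: fewer than 5 valid ring frames")
  t <- trace$time_s
  A <- trace$area_um2
  n <- nrow(trace)

  # formation: first run of k consecutive valid frames
  run <- rle(ok)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  fi <- starts[run$values & run$lengths >= k_formation][1]
  if (is.na(fi))
    abort_event("event detection failed: no ", k_formation,
                " consecutive frames with a ring (formation)")
  formation_s <- t[fi]

  valid_after <- which(ok & seq_len(n) >= fi)
  peak <- max(A[valid_after])
  completion_s <- NA_real_
  below <- valid_after[A[valid_after] <= closure_fraction * peak]
  if (length(below)) {
    completion_s <- t[below[1]]
  } else {
    # ring vanishes after sustained contraction
    last_valid <- max(valid_after)
    if (last_valid < n && A[last_valid] < 0.5 * peak &&
        all(!ok[(last_valid + 1L):n]))
      completion_s <- t[last_valid + 1L]
  }

  plateau <- NULL
  if (!is.null(loading_schedule)) {
    ls <- loading_schedule[1]; le <- loading_schedule[2]
    sched <- which(ok & t >= ls & t <= le)
    pre <- which(ok & t >= formation_s & t < ls)
    if (length(sched) >= 3L && length(pre) >= 3L) {
      pre_rate <- abs(unname(coef(lm(A[pre] ~ t[pre]))[2]))
      slopes <- local_slopes(t[sched], A[sched], slope_window_s)
      stalled <- abs(slopes) < stall_fraction * pre_rate
      if (any(stalled)) {
        run <- rle(stalled)
        ends <- cumsum(run$lengths)
        starts <- ends - run$lengths + 1L
        best <- which(run$values)[which.max(run$lengths[run$values])]
        sel <- sched[starts[best]:ends[best]]
        plateau <- list(start_s = t[sel[1]], end_s = t[sel[length(sel)]],
                        radius_um = mean(trace$radius_um[sel]))
      }
    }
  }
  structure(list(formation_s = formation_s, plateau = plateau,
                 completion_s = completion_s),
            class = "event_times")
}

# slope of area vs time in a +/- window/2 neighbourhood of each point
local_slopes <- function(t, y, window_s) {
  vapply(seq_along(t), function(i) {
    sel <- abs(t - t[i]) <= window_s / 2
    if (sum(sel) < 3L) return(NA_real_)
    unname(coef(lm(y[sel] ~ t[sel]))[2])
  }, numeric(1))
}

#' @export
print.event_times <- function(x, ...) {
  cat("Ring events:\n")
  cat(sprintf("  formation:  %s s\n", format(x$formation_s)))
  if (!is.null(x$plateau))
    cat(sprintf("  plateau:    %g-%g s, counter-balanced R = %.3f um\n",
                x$plateau$start_s, x$plateau$end_s, x$plateau$radius_um))
  cat(sprintf("  completion: %s s\n", format(x$completion_s)))
  invisible(x)
}

#' Read / write ring traces and event times
#'
#' Traces are CSV with header `time_s,area_um2,radius_um,flag`; event times
#' are JSON.
#'
#' @param trace a `ring_trace`.
#' @param path file path.
#' @name trace_io
#' @export
write_ring_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_ring_trace <- function(path, pixel_size_um = NULL,
                            frame_interval_s = NULL) {
  tab <- read.csv(path)
  if (!all(c("time_s", "area_um2", "radius_um", "flag") %in% names(tab)))
    abort_invalid("not a ring trace: ", path)
  attr(tab, "pixel_size_um") <- pixel_size_um
  attr(tab, "frame_interval_s") <- frame_interval_s
  class(tab) <- c("ring_trace", "data.frame")
  tab
}

#' @rdname trace_io
#' @param events an `event_times`.
#' @export
write_event_times <- function(events, path) {
  jsonlite::write_json(unclass(events), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
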