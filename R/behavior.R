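# Floating circular-track behavior processing: track geometry, per-frame
# aggregation of tracker samples, movement filtering, lap segmentation.

#' Build the circular-track geometry
#'
#' The track is an annulus between an outer arena wall and an inner
#' circle; positions are linearized along the midline circle. With the
#' default 250 mm outer and 140 mm inner diameters the midline
#' circumference is 61.26 cm, divided into 72 equal bins of ~0.85 cm.
#'
#' @param outer_diameter_mm outer arena diameter in mm.
#' @param inner_diameter_mm inner circle diameter in mm.
#' @param n_bins number of equal position bins along the midline.
#' @return an object of class `track_geometry`: a list with the
#'   diameters, `midline_circumference_cm`, `n_bins`, `bin_length_cm`
#'   and half-open `bin_edges_cm` covering `[0, circumference)`.
#' @export
make_track <- function(outer_diameter_mm = 250, inner_diameter_mm = 140,
                       n_bins = 72) {
  stopifnot(outer_diameter_mm > inner_diameter_mm, inner_diameter_mm >= 0,
            n_bins >= 1)
  circ_cm <- pi * (outer_diameter_mm + inner_diameter_mm) / 2 / 10
  structure(list(
    outer_diameter_mm = outer_diameter_mm,
    inner_diameter_mm = inner_diameter_mm,
    midline_circumference_cm = circ_cm,
    n_bins = as.integer(n_bins),
    bin_length_cm = circ_cm / n_bins,
    bin_edges_cm = seq(0, circ_cm, length.out = n_bins + 1)
  ), class = "track_geometry")
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf(
    "Circular track: outer %g mm, inner %g mm\n  midline circumference %.2f cm, %d bins of %.3f cm\n",
    x$outer_diameter_mm, x$inner_diameter_mm, x$midline_circumference_cm,
    x$n_bins, x$bin_length_cm))
  invisible(x)
}

# map linear positions (cm) to 1-based bin indices
position_to_bin <- function(position_cm, track) {
  b <- floor(position_cm / track$bin_length_cm) + 1L
  pmin(pmax(b, 1L), track$n_bins)
}

#' Aggregate tracker samples to imaging frames
#'
#' The tracker samples faster than the stored imaging rate; all samples
#' falling within a frame interval `[t_k, t_{k+1})` are reduced to their
#' median. The polar angle uses the circular median; speed, heading and
#' x/y use the ordinary median. Frames with no samples carry the
#' previous frame's values forward and are flagged.
#'
#' @param samples data frame with columns `time_s`, `angle_deg`,
#'   `speed_mm_s`, and optionally `x_mm`, `y_mm`, `heading_deg`.
#' @param frame_times_s strictly increasing frame start times (s).
#' @return data frame with one row per frame: `frame_time_s`,
#'   `angle_rad`, `speed_mm_s`, `heading_deg`, `x_mm`, `y_mm`,
#'   `n_samples`, `imputed`.
#' @export
aggregate_to_frames <- function(samples, frame_times_s) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0,
            all(diff(frame_times_s) > 0))
  if (!all(c("time_s", "angle_deg", "speed_mm_s") %in% names(samples)))
    stop("samples must have columns time_s, angle_deg, speed_mm_s")
  nf <- length(frame_times_s)
  dt <- median(diff(frame_times_s))
  edges <- c(frame_times_s, frame_times_s[nf] + dt)
  grp <- findInterval(samples$time_s, edges, rightmost.closed = FALSE)
  inside <- grp >= 1 & grp <= nf
  if (!any(inside)) stop("no tracker samples fall within the frame grid")
  grp <- grp[inside]
  sm <- samples[inside, , drop = FALSE]

  med_by <- function(v) {
    out <- rep(NA_real_, nf)
    agg <- tapply(v, grp, median, na.rm = TRUE)
    out[as.integer(names(agg))] <- agg
    out
  }
  ang <- rep(NA_real_, nf)
  agg <- tapply(sm$angle_deg * pi / 180, grp, circ_median)
  ang[as.integer(names(agg))] <- agg

  out <- data.frame(
    frame_time_s = frame_times_s,
    angle_rad = ang,
    speed_mm_s = med_by(sm$speed_mm_s),
    heading_deg = if ("heading_deg" %in% names(sm)) med_by(sm$heading_deg) else NA_real_,
    x_mm = if ("x_mm" %in% names(sm)) med_by(sm$x_mm) else NA_real_,
    y_mm = if ("y_mm" %in% names(sm)) med_by(sm$y_mm) else NA_real_
  )
  cnt <- tabulate(grp, nbins = nf)
  out$n_samples <- cnt
  out$imputed <- cnt == 0L
  # carry forward previous values for empty frames
  for (col in c("angle_rad", "speed_mm_s", "heading_deg", "x_mm", "y_mm")) {
    v <- out[[col]]
    for (i in seq_len(nf)[-1]) if (is.na(v[i]) && out$imputed[i]) v[i] <- v[i - 1]
    if (is.na(v[1])) v[1] <- v[which(!is.na(v))[1]]
    out[[col]] <- v
  }
  out
}

#' Movement mask from instantaneous speed
#'
#' Smooths speed with a 0.5 s moving average, keeps periods longer than
#' `min_dur_s` with smoothed speed above `threshold` (20 mm/s), and
#' dilates each kept period by `buffer_s` on both sides.
#'
#' @param speed_mm_s per-frame speed (mm/s).
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param threshold speed threshold in mm/s.
#' @param min_dur_s minimal supra-threshold duration (s), exclusive.
#' @param buffer_s dilation added to each kept period (s).
#' @param smooth logical; smooth speed before thresholding.
#' @return logical vector, `TRUE` for frames treated as moving.
#' @export
movement_mask <- function(speed_mm_s, frame_rate_hz, threshold = 20,
                          min_dur_s = 1.0, buffer_s = 0.5, smooth = TRUE) {
  stopifnot(all(is.finite(speed_mm_s)), frame_rate_hz > 0)
  n <- length(speed_mm_s)
  sp <- if (smooth) moving_average(speed_mm_s, round(0.5 * frame_rate_hz)) else speed_mm_s
  above <- sp > threshold
  keep <- logical(n)
  runs <- true_runs(above)
  min_frames <- min_dur_s * frame_rate_hz
  buf <- round(buffer_s * frame_rate_hz)
  if (nrow(runs) > 0) {
    for (r in seq_len(nrow(runs))) {
      len <- runs[r, "end"] - runs[r, "start"] + 1
      if (len > min_frames) {
        lo <- max(1L, runs[r, "start"] - buf)
        hi <- min(n, runs[r, "end"] + buf)
        keep[lo:hi] <- TRUE
      }
    }
  }
  keep
}

#' Segment laps from the unwrapped track angle
#'
#' A lap boundary is placed each time the accumulated signed rotation
#' since the previous boundary reaches a full 2*pi (net rotation, so
#' direction reversals must be made up before a lap completes).
#' Partial laps at the session edges are unassigned (`lap_id = -1`).
#' Laps whose mean instantaneous speed exceeds `fast_lap_mm_s` are
#' flagged `lap_kept = FALSE` (slow calcium signals cannot be assigned
#' to the small spatial bins at such speeds).
#'
#' @param angle_rad per-frame track angle (rad).
#' @param speed_mm_s per-frame speed (mm/s), used for the fast-lap rule.
#' @param fast_lap_mm_s mean-speed threshold above which a lap is dropped.
#' @return list with `lap_id` (integer per frame, -1 when unassigned)
#'   and `lap_kept` (logical per completed lap).
#' @export
segment_laps <- function(angle_rad, speed_mm_s = NULL, fast_lap_mm_s = 180) {
  stopifnot(is.numeric(angle_rad))
  n <- length(angle_rad)
  u <- unwrap_angle(angle_rad)
  acc <- u - u[1]
  lap_id <- rep(-1L, n)
  boundaries <- integer(0)
  origin <- 0
  lap <- 0L
  for (i in seq_len(n)) {
    if (abs(acc[i] - origin) >= 2 * pi) {
      lap <- lap + 1L
      # all frames since previous boundary belong to this completed lap
      start <- if (length(boundaries)) boundaries[length(boundaries)] + 1L else 1L
      lap_id[start:i] <- lap
      boundaries <- c(boundaries, i)
      origin <- origin + 2 * pi * sign(acc[i] - origin)
    }
  }
  n_laps <- lap
  if (n_laps == 0) {
    warning("no completed laps in session")
    return(list(lap_id = lap_id, lap_kept = logical(0)))
  }
  lap_kept <- rep(TRUE, n_laps)
  if (!is.null(speed_mm_s)) {
    for (l in seq_len(n_laps)) {
      ms <- mean(speed_mm_s[lap_id == l], na.rm = TRUE)
      if (is.finite(ms) && ms > fast_lap_mm_s) lap_kept[l] <- FALSE
    }
  }
  list(lap_id = lap_id, lap_kept = lap_kept)
}

#' Process a raw behavior session to per-frame state
#'
#' Convenience wrapper chaining [aggregate_to_frames()],
#' [movement_mask()] and [segment_laps()], adding linearized position
#' along the track midline.
#'
#' @param samples tracker sample table (see [aggregate_to_frames()]).
#' @param frame_times_s imaging frame times (s).
#' @param track a [make_track()] geometry.
#' @param ... passed to [movement_mask()] / [segment_laps()]
#'   (`threshold`, `min_dur_s`, `buffer_s`, `fast_lap_mm_s`).
#' @return data frame of per-frame behavioral state (`position_cm`,
#'   `moving`, `lap_id`, ...) with `lap_kept` attached as an attribute.
#' @export
process_behavior <- function(samples, frame_times_s, track,
                             threshold = 20, min_dur_s = 1.0,
                             buffer_s = 0.5, fast_lap_mm_s = 180, ...) {
  fr <- aggregate_to_frames(samples, frame_times_s)
  rate <- 1 / median(diff(frame_times_s))
  fr$position_cm <- wrap_2pi(fr$angle_rad) / (2 * pi) *
    track$midline_circumference_cm
  fr$moving <- movement_mask(fr$speed_mm_s, rate, threshold = threshold,
                             min_dur_s = min_dur_s, buffer_s = buffer_s)
  laps <- segment_laps(fr$angle_rad, fr$speed_mm_s,
                       fast_lap_mm_s = fast_lap_mm_s)
  fr$lap_id <- laps$lap_id
  attr(fr, "lap_kept") <- laps$lap_kept
  attr(fr, "frame_rate_hz") <- rate
  fr
}
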