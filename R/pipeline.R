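# Configuration defaults and end-to-end orchestration
# (behavior -> signals -> tuning).

#' Default pipeline configuration
#'
#' All analysis constants at their published defaults: 72 track bins,
#' 20 mm/s movement threshold over >1 s with 0.5 s buffers, 180 mm/s
#' fast-lap removal, 500 consistency iterations at KS alpha 0.01 with
#' Cohen's D > 0.5, Gaussian-field criteria (adjusted R^2 > 0.375,
#' 2.5 cm < FWHM < half-track, A > 0, A/A0 > 0.5), 100 speed-score
#' shuffles gated at the 99%/1% percentiles with a 10-frame minimum
#' shift, 1 um^2 spine inclusion, 10 um dendrite sections, 50 um
#' histology bins and 1000 bootstrap resamples.
#'
#' @param ... overrides of any default by name.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_bins = 72, outer_diameter_mm = 250, inner_diameter_mm = 140,
    speed_threshold_mm_s = 20, min_move_dur_s = 1.0, move_buffer_s = 0.5,
    fast_lap_mm_s = 180,
    n_consistency_iter = 500, ks_alpha = 0.01, cohens_d_min = 0.5,
    adj_r2_min = 0.375, fwhm_min_cm = 2.5, amp_ratio_min = 0.50,
    n_speed_shuffles = 100, min_shift_frames = 10,
    spine_min_area_um2 = 1, section_um = 10,
    histology_bin_um = 50, n_boot = 1000,
    seed = 1)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  bad <- c("fwhm_min_cm", "min_move_dur_s", "spine_min_area_um2")
  for (nm in bad) if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
    stop("invalid configuration value for ", nm)
  cfg
}

#' Run the session pipeline on raw inputs
#'
#' Executes behavior processing, trace post-processing (neuropil
#' subtraction, dF/F, deconvolution, QC) and cell classification,
#' returning a structured session report. All randomness derives from
#' `config$seed`.
#'
#' @param samples tracker sample table (see [aggregate_to_frames()]).
#' @param frame_times_s imaging frame times (s).
#' @param f_soma,f_neuropil cells x frames fluorescence matrices.
#' @param config a [default_config()] list.
#' @param output_dir optional directory; when given, per-cell CSV and
#'   a JSON summary are written.
#' @return list of class `session_report`: `track`, `frames`, `cells`
#'   (per-cell statistics table), `summary` (category counts, lap
#'   counts, QC flags), `config`.
#' @export
run_pipeline <- function(samples, frame_times_s, f_soma, f_neuropil,
                         config = default_config(), output_dir = NULL) {
  stopifnot(is.matrix(f_soma), is.matrix(f_neuropil),
            all(dim(f_soma) == dim(f_neuropil)),
            ncol(f_soma) == length(frame_times_s))
  track <- make_track(config$outer_diameter_mm, config$inner_diameter_mm,
                      config$n_bins)
  frames <- process_behavior(samples, frame_times_s, track,
                             threshold = config$speed_threshold_mm_s,
                             min_dur_s = config$min_move_dur_s,
                             buffer_s = config$move_buffer_s,
                             fast_lap_mm_s = config$fast_lap_mm_s)
  rate_hz <- attr(frames, "frame_rate_hz")
  nc <- nrow(f_soma)
  dff <- matrix(NA_real_, nc, ncol(f_soma))
  rates <- matrix(NA_real_, nc, ncol(f_soma))
  alpha <- f0 <- numeric(nc)
  qc <- character(nc)
  for (j in seq_len(nc)) {
    pr <- process_trace(f_soma[j, ], f_neuropil[j, ], rate_hz)
    alpha[j] <- pr$alpha; f0[j] <- pr$f0
    if (pr$baseline_valid) {
      dff[j, ] <- pr$dff; rates[j, ] <- pr$rates
      qc[j] <- qc_rate_flags(pr$rates, frames$moving, rate_hz)
    } else qc[j] <- "undetermined"
  }
  cells <- classify_cells(dff, rates, frames, track,
                          n_iter = config$n_consistency_iter,
                          n_shuffles = config$n_speed_shuffles,
                          seed = config$seed)
  cells$alpha <- alpha; cells$f0 <- f0; cells$qc_flag <- qc
  lap_kept <- attr(frames, "lap_kept")
  summary <- list(
    n_cells = nc,
    n_place = sum(cells$category == "place"),
    n_speed = sum(cells$category == "speed"),
    n_conjunctive = sum(cells$category == "conjunctive"),
    n_none = sum(cells$category == "none"),
    n_laps = length(lap_kept), n_laps_kept = sum(lap_kept),
    frac_moving = mean(frames$moving),
    qc = table(qc))
  report <- structure(list(track = track, frames = frames, cells = cells,
                           summary = summary, config = config),
                      class = "session_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells, file.path(output_dir, "cells.csv"), row.names = FALSE)
    jsonlite::write_json(summary[names(summary) != "qc"],
                         file.path(output_dir, "session_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.session_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Session: %d cells | %d laps (%d kept) | moving %.0f%%\n",
    s$n_cells, s$n_laps, s$n_laps_kept, 100 * s$frac_moving))
  cat(sprintf("  place %d | speed %d | conjunctive %d | none %d\n",
              s$n_place, s$n_speed, s$n_conjunctive, s$n_none))
  invisible(x)
}
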