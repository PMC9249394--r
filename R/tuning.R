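# Place/speed-cell classification and spatial information on the
# 72-bin circular track.

#' Per-lap spatial tuning curves
#'
#' For each kept lap, activity during moving frames is summed in each
#' track bin and divided by the occupancy time of that bin; the mean
#' curve averages across laps, ignoring unoccupied (missing) bins.
#'
#' @param activity per-frame activity (dF/F or inferred rate).
#' @param position_cm per-frame linearized position (cm).
#' @param moving logical moving mask.
#' @param lap_id per-frame lap index (-1 unassigned).
#' @param track a [make_track()] geometry.
#' @param lap_kept logical per completed lap; dropped laps are skipped.
#' @param dt_s frame duration (s); only scales curves, default 1 frame.
#' @return list with `per_lap_curves` (kept-lap x n_bins matrix, NA for
#'   unoccupied bins), `mean_curve`, `occupancy_s` (total per bin) and
#'   `kept_laps` (original lap indices of the rows).
#' @export
spatial_tuning_curves <- function(activity, position_cm, moving, lap_id,
                                  track, lap_kept = NULL, dt_s = 1) {
  n <- length(activity)
  stopifnot(length(position_cm) == n, length(moving) == n,
            length(lap_id) == n)
  laps <- sort(unique(lap_id[lap_id > 0]))
  if (!is.null(lap_kept) && length(lap_kept))
    laps <- laps[lap_kept[laps]]
  nb <- track$n_bins
  bins <- position_to_bin(position_cm, track)
  curves <- matrix(NA_real_, length(laps), nb)
  occ_total <- numeric(nb)
  for (i in seq_along(laps)) {
    sel <- moving & lap_id == laps[i]
    if (!any(sel)) next
    occ <- tabulate(bins[sel], nbins = nb) * dt_s
    act <- rep(0, nb)
    tb <- tapply(activity[sel], factor(bins[sel], levels = seq_len(nb)), sum)
    act[!is.na(tb)] <- tb[!is.na(tb)]
    curves[i, occ > 0] <- act[occ > 0] / occ[occ > 0]
    occ_total <- occ_total + occ
  }
  mean_curve <- colMeans(curves, na.rm = TRUE)
  mean_curve[!is.finite(mean_curve)] <- NA_real_
  list(per_lap_curves = curves, mean_curve = mean_curve,
       occupancy_s = occ_total, kept_laps = laps)
}

# circularly shift each row of a matrix by its own offset (in bins)
shift_rows_circular <- function(m, shifts) {
  nb <- ncol(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    k <- shifts[i] %% nb
    if (k > 0) out[i, ] <- m[i, c((nb - k + 1):nb, 1:(nb - k))]
  }
  out
}

# correlation between mean curves of a random half split of laps
split_half_corr <- function(curves, perm) {
  nl <- nrow(curves)
  h1 <- perm[1:ceiling(nl / 2)]
  h2 <- perm[(ceiling(nl / 2) + 1):nl]
  m1 <- colMeans(curves[h1, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(curves[h2, , drop = FALSE], na.rm = TRUE)
  ok <- is.finite(m1) & is.finite(m2)
  if (sum(ok) < 3 || sd(m1[ok]) == 0 || sd(m2[ok]) == 0) return(NA_real_)
  cor(m1[ok], m2[ok])
}

#' Split-half consistency test with circular-permutation null
#'
#' The laps are randomly split in half 500 times and the correlation of
#' the two split-mean tuning curves recorded (real distribution). The
#' null distribution repeats this after independently circularly
#' permuting each lap's curve by a random number of bins (drawn fresh
#' each iteration). A cell is consistent if a two-sample
#' Kolmogorov-Smirnov test rejects at `alpha` AND Cohen's D between
#' the two correlation distributions exceeds `d_min`.
#'
#' In addition to the two distribution tests, the mean real split-half
#' correlation must exceed the `mean_gate_q` quantile of the shuffled
#' values: the KS and Cohen's D statistics compare a distribution
#' conditioned on the one observed session against the permutation
#' marginal, so their null spread is set by the bin count rather than
#' the lap count and they alone admit chance "consistency" on
#' structureless data; the percentile gate against the same
#' circular-permutation null restores a calibrated false-positive
#' rate (see the methods vignette).
#'
#' @param per_lap_curves kept-lap x n_bins matrix.
#' @param n_iter iterations for both distributions.
#' @param alpha KS significance level.
#' @param d_min minimal Cohen's D.
#' @param mean_gate_q quantile of the shuffled correlations that the
#'   mean real correlation must exceed (set to `NA` to disable).
#' @param seed integer seed for splits and permutations.
#' @return list with `real_split_corrs`, `shuffle_split_corrs`, `ks_p`,
#'   `cohens_d`, `consistent`.
#' @export
consistency_test <- function(per_lap_curves, n_iter = 500, alpha = 0.01,
                             d_min = 0.5, mean_gate_q = 0.99, seed = 1) {
  nl <- nrow(per_lap_curves)
  if (nl < 6) stop("consistency test requires at least 6 kept laps")
  nb <- ncol(per_lap_curves)
  set.seed(seed)
  real <- vapply(seq_len(n_iter), function(i)
    split_half_corr(per_lap_curves, sample.int(nl)), numeric(1))
  shuf <- vapply(seq_len(n_iter), function(i) {
    shifted <- shift_rows_circular(per_lap_curves,
                                   sample.int(nb - 1, nl, replace = TRUE))
    split_half_corr(shifted, sample.int(nl))
  }, numeric(1))
  real_ok <- real[is.finite(real)]
  shuf_ok <- shuf[is.finite(shuf)]
  if (length(real_ok) < 10 || length(shuf_ok) < 10) {
    return(list(real_split_corrs = real, shuffle_split_corrs = shuf,
                ks_p = NA_real_, cohens_d = NA_real_, consistent = FALSE))
  }
  ks_p <- suppressWarnings(ks.test(real_ok, shuf_ok)$p.value)
  pooled_sd <- sqrt(((length(real_ok) - 1) * var(real_ok) +
                     (length(shuf_ok) - 1) * var(shuf_ok)) /
                    (length(real_ok) + length(shuf_ok) - 2))
  d <- if (pooled_sd > 0) (mean(real_ok) - mean(shuf_ok)) / pooled_sd else 0
  gate <- if (is.na(mean_gate_q)) TRUE else
    mean(real_ok) > quantile(shuf_ok, mean_gate_q, names = FALSE)
  list(real_split_corrs = real, shuffle_split_corrs = shuf,
       ks_p = ks_p, cohens_d = d,
       consistent = is.finite(ks_p) && ks_p < alpha && d > d_min && gate)
}

#' Gaussian place-field fit with acceptance criteria
#'
#' The mean tuning curve is circularly recentered on its maximum (to
#' handle wraparound) and fit with
#' `R = A0 + A * exp(-((x - B)/C)^2)` by nonlinear least squares.
#' `FWHM = 2*C*sqrt(ln 2)`. The four field criteria are: adjusted
#' R^2 > 0.375; 2.5 cm < FWHM < half the track length; A > 0; and
#' A/A0 > 0.50 (A0 clamped to 1e-6 when non-positive, flagged).
#'
#' @param mean_curve length-n_bins tuning curve (NA allowed).
#' @param track a [make_track()] geometry.
#' @param adj_r2_min,fwhm_min_cm,amp_ratio_min criterion thresholds.
#' @return list with `fit_params` (A0, A, B, C), `adj_r2`, `fwhm_cm`,
#'   `criteria` (logical 4-vector), `criteria_pass`, `field_center_cm`,
#'   `a0_clamped`, `converged`.
#' @export
fit_gaussian_field <- function(mean_curve, track, adj_r2_min = 0.375,
                               fwhm_min_cm = 2.5, amp_ratio_min = 0.50) {
  nb <- track$n_bins
  stopifnot(length(mean_curve) == nb)
  fwhm_max_cm <- track$midline_circumference_cm / 2
  ok <- is.finite(mean_curve)
  fail <- list(fit_params = c(A0 = NA, A = NA, B = NA, C = NA),
               adj_r2 = NA_real_, fwhm_cm = NA_real_,
               criteria = rep(FALSE, 4), criteria_pass = FALSE,
               field_center_cm = NA_real_, a0_clamped = FALSE,
               converged = FALSE)
  if (sum(ok) < 0.8 * nb || sd(mean_curve[ok]) == 0) return(fail)

  peak_bin <- which.max(ifelse(ok, mean_curve, -Inf))
  center_bin <- floor(nb / 2) + 1
  shift <- (center_bin - peak_bin) %% nb
  idx <- ((seq_len(nb) - 1 - shift) %% nb) + 1
  y <- mean_curve[idx]
  x <- (seq_len(nb) - 0.5) * track$bin_length_cm
  use <- is.finite(y)
  xs <- x[use]; ys <- y[use]

  start <- list(A0 = max(min(ys), 1e-3), A = max(ys) - min(ys),
                B = x[center_bin], C = 5)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A0 + A * exp(-((xs - B) / C)^2), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  p["C"] <- abs(p["C"])
  rss <- sum((ys - fitted(fit))^2)
  tss <- sum((ys - mean(ys))^2)
  n <- length(ys); npar <- 4
  adj_r2 <- 1 - (rss / (n - npar)) / (tss / (n - 1))
  fwhm <- 2 * p["C"] * sqrt(log(2))
  a0_clamped <- p["A0"] <= 0
  a0_eff <- max(p["A0"], 1e-6)
  criteria <- c(adj_r2 > adj_r2_min,
                fwhm > fwhm_min_cm && fwhm < fwhm_max_cm,
                p["A"] > 0,
                p["A"] / a0_eff > amp_ratio_min)
  # map fitted center back to track coordinates (undo the recentering)
  center <- (p["B"] - shift * track$bin_length_cm) %%
    track$midline_circumference_cm
  list(fit_params = p, adj_r2 = unname(adj_r2), fwhm_cm = unname(fwhm),
       criteria = unname(criteria), criteria_pass = all(criteria),
       field_center_cm = unname(center), a0_clamped = a0_clamped,
       converged = TRUE)
}

#' Place-cell decision from consistency and field fit
#'
#' A place cell must pass the split-half consistency test and all four
#' Gaussian-field criteria; its field center is the fitted peak mapped
#' to track coordinates and its width the fitted FWHM.
#'
#' @param consistency result of [consistency_test()].
#' @param fit result of [fit_gaussian_field()].
#' @return list `place_cell`, `field_center_cm`, `fwhm_cm`.
#' @export
classify_place_cell <- function(consistency, fit) {
  pc <- isTRUE(consistency$consistent) && isTRUE(fit$criteria_pass)
  list(place_cell = pc,
       field_center_cm = if (pc) fit$field_center_cm else NA_real_,
       fwhm_cm = if (pc) fit$fwhm_cm else NA_real_)
}

#' Speed score with circular-shuffle gates
#'
#' The speed score is the Pearson correlation of the full dF/F trace
#' with running speed. The null circularly shifts the dF/F trace
#' `n_shuffles` times by uniform offsets of at least `min_shift_frames`
#' frames; a speed cell scores above the 99th (positive) or below the
#' 1st (negative) percentile of the shuffled scores.
#'
#' @param dff dF/F trace.
#' @param speed_mm_s aligned speed trace.
#' @param n_shuffles number of circular shuffles.
#' @param min_shift_frames minimal circular shift.
#' @param seed integer seed.
#' @param upper_q,lower_q percentile gates.
#' @return list `speed_score`, `shuffle_scores`, `speed_cell`,
#'   `speed_sign` ("+", "-", or "none").
#' @export
speed_score <- function(dff, speed_mm_s, n_shuffles = 100,
                        min_shift_frames = 10, seed = 1,
                        upper_q = 0.99, lower_q = 0.01) {
  n <- length(dff)
  stopifnot(length(speed_mm_s) == n, n > 2 * min_shift_frames)
  if (sd(dff) == 0 || sd(speed_mm_s) == 0)
    stop("constant trace; speed score undefined")
  score <- cor(dff, speed_mm_s)
  set.seed(seed)
  shifts <- sample(seq(min_shift_frames, n - min_shift_frames), n_shuffles,
                   replace = TRUE)
  shuf <- vapply(shifts, function(k)
    cor(dff[c((k + 1):n, 1:k)], speed_mm_s), numeric(1))
  hi <- quantile(shuf, upper_q, names = FALSE)
  lo <- quantile(shuf, lower_q, names = FALSE)
  sign <- if (score > hi) "+" else if (score < lo) "-" else "none"
  list(speed_score = score, shuffle_scores = shuf,
       speed_cell = sign != "none", speed_sign = sign)
}

#' Skaggs spatial information (bits per inferred spike)
#'
#' `SI = (1/abar) * sum_k p(k) a(k) log2(a(k)/abar)` over the track
#' bins, with `p(k)` the occupancy probability, `a(k)` the mean
#' inferred rate in bin `k` and `abar` the occupancy-weighted overall
#' mean rate; zero-rate bins contribute 0.
#'
#' @param rates per-frame inferred event rate (nonnegative).
#' @param position_cm per-frame position (cm).
#' @param moving logical moving mask.
#' @param track a [make_track()] geometry.
#' @return spatial information in bits/inferred spike, or `NA` when the
#'   total rate is zero (cell excluded).
#' @export
spatial_information <- function(rates, position_cm, moving, track) {
  sel <- moving & is.finite(rates)
  if (!any(sel)) return(NA_real_)
  r <- rates[sel]
  b <- position_to_bin(position_cm[sel], track)
  nb <- track$n_bins
  occ <- tabulate(b, nbins = nb)
  p <- occ / sum(occ)
  a <- rep(0, nb)
  tb <- tapply(r, factor(b, levels = seq_len(nb)), mean)
  a[!is.na(tb)] <- tb[!is.na(tb)]
  abar <- sum(p * a)
  if (abar <= 0) return(NA_real_)
  terms <- ifelse(a > 0, p * a * log2(a / abar), 0)
  sum(terms) / abar
}

#' Classify every cell of a session
#'
#' Runs tuning curves, consistency, Gaussian field fit, place-cell
#' decision, speed score and spatial information for each cell.
#'
#' @param dff cells x frames dF/F matrix (activity for tuning curves
#'   and speed scores).
#' @param rates cells x frames inferred-rate matrix (for SI); may be
#'   `NULL` to skip SI.
#' @param frames behavior frame table from [process_behavior()].
#' @param track a [make_track()] geometry.
#' @param n_iter,n_shuffles,seed statistics parameters; the per-cell
#'   seeds are derived deterministically from `seed`.
#' @return data frame with one row per cell: `consistent`, `ks_p`,
#'   `cohens_d`, `adj_r2`, `fwhm_cm`, `place_cell`, `field_center_cm`,
#'   `speed_score`, `speed_cell`, `speed_sign`, `si_bits_per_spike`,
#'   `category` (place / speed / conjunctive / none).
#' @export
classify_cells <- function(dff, rates = NULL, frames, track,
                           n_iter = 500, n_shuffles = 100, seed = 1) {
  stopifnot(is.matrix(dff), ncol(dff) == nrow(frames))
  lap_kept <- attr(frames, "lap_kept")
  rate_hz <- attr(frames, "frame_rate_hz") %||%
    (1 / median(diff(frames$frame_time_s)))
  ncell <- nrow(dff)
  out <- vector("list", ncell)
  for (j in seq_len(ncell)) {
    cell_seed <- (seed * 10007L + j) %% .Machine$integer.max
    tc <- spatial_tuning_curves(dff[j, ], frames$position_cm, frames$moving,
                                frames$lap_id, track, lap_kept,
                                dt_s = 1 / rate_hz)
    cons <- if (nrow(tc$per_lap_curves) >= 6)
      consistency_test(tc$per_lap_curves, n_iter = n_iter, seed = cell_seed)
    else list(ks_p = NA, cohens_d = NA, consistent = FALSE)
    fit <- fit_gaussian_field(tc$mean_curve, track)
    pc <- classify_place_cell(cons, fit)
    ss <- tryCatch(
      speed_score(dff[j, ], frames$speed_mm_s, n_shuffles = n_shuffles,
                  seed = cell_seed),
      error = function(e) list(speed_score = NA_real_, speed_cell = FALSE,
                               speed_sign = "none"))
    si <- if (!is.null(rates))
      spatial_information(rates[j, ], frames$position_cm, frames$moving,
                          track)
    else NA_real_
    category <- if (pc$place_cell && ss$speed_cell) "conjunctive"
      else if (pc$place_cell) "place"
      else if (ss$speed_cell) "speed" else "none"
    out[[j]] <- data.frame(
      cell = j, consistent = cons$consistent, ks_p = cons$ks_p,
      cohens_d = cons$cohens_d, adj_r2 = fit$adj_r2,
      fwhm_cm = fit$fwhm_cm, place_cell = pc$place_cell,
      field_center_cm = pc$field_center_cm, speed_score = ss$speed_score,
      speed_cell = ss$speed_cell, speed_sign = ss$speed_sign,
      si_bits_per_spike = si, category = category)
  }
  do.call(rbind, out)
}

#' Circularly time-shuffle each lap of an activity trace
#'
#' Within each lap's frames, the activity is circularly shifted by a
#' random offset. Used as the false-positive control for the place-cell
#' classifier: lap-wise time shuffling destroys position locking while
#' preserving each lap's amplitude distribution.
#'
#' @param activity cells x frames matrix (or a vector for one cell).
#' @param lap_id per-frame lap index.
#' @param seed integer seed.
#' @return shuffled matrix/vector of the same shape.
#' @export
lap_time_shuffle <- function(activity, lap_id, seed = 1) {
  vec <- is.null(dim(activity))
  m <- if (vec) matrix(activity, nrow = 1) else activity
  set.seed(seed)
  for (l in unique(lap_id[lap_id > 0])) {
    idx <- which(lap_id == l)
    nl <- length(idx)
    if (nl < 2) next
    for (j in seq_len(nrow(m))) {
      k <- sample.int(nl - 1, 1)
      m[j, idx] <- m[j, idx[c((k + 1):nl, 1:k)]]
    }
  }
  if (vec) m[1, ] else m
}
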