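# Synthetic session generator: floating-track behavior and a calcium
# population with known ground truth (place, speed, conjunctive, none).

#' Specification for a synthetic imaging session
#'
#' Defaults describe a typical good-SNR slow-indicator recording on the
#' floating circular track: 600 s at 10 Hz stored frames with 40 Hz
#' tracking, ~30% place cells with 15 cm-wide fields, per-event dF/F
#' amplitude 0.5 against frame noise of sd 0.05.
#'
#' @param n_cells number of cells.
#' @param frac_place,frac_speed,frac_conjunctive category fractions
#'   (must sum to <= 1; remainder is untuned).
#' @param field_width_cm FWHM of generated place fields (cm).
#' @param transient_amplitude dF/F amplitude per unit event.
#' @param noise_sd per-frame Gaussian noise sd in dF/F units.
#' @param neuropil_gain fraction of the shared neuropil signal mixed
#'   into each soma trace.
#' @param frame_rate_hz stored imaging rate (Hz).
#' @param duration_s session duration (s).
#' @param seed integer seed; identical seeds give identical sessions.
#' @return a `sim_session_spec` list.
#' @export
sim_session_spec <- function(n_cells = 100, frac_place = 0.3,
                             frac_speed = 0.1, frac_conjunctive = 0.05,
                             field_width_cm = 15, transient_amplitude = 0.5,
                             noise_sd = 0.05, neuropil_gain = 0.3,
                             frame_rate_hz = 10, duration_s = 600,
                             seed = 1) {
  if (frac_place + frac_speed + frac_conjunctive > 1 + 1e-12)
    stop("category fractions must sum to at most 1")
  if (any(c(frac_place, frac_speed, frac_conjunctive) < 0) ||
      field_width_cm <= 0)
    stop("fractions and field width must be nonnegative")
  if (duration_s <= 0 || frame_rate_hz <= 0)
    stop("duration and frame rate must be positive")
  structure(list(
    n_cells = as.integer(n_cells), frac_place = frac_place,
    frac_speed = frac_speed, frac_conjunctive = frac_conjunctive,
    field_width_cm = field_width_cm,
    transient_amplitude = transient_amplitude, noise_sd = noise_sd,
    neuropil_gain = neuropil_gain, frame_rate_hz = frame_rate_hz,
    duration_s = duration_s, seed = as.integer(seed)
  ), class = "sim_session_spec")
}

#' Simulate floating-track behavior
#'
#' Tracker samples at 4x the imaging rate (40 Hz for 10 Hz frames),
#' alternating run epochs (lognormal mean speeds around 110 mm/s,
#' occasionally above the 180 mm/s fast-lap threshold) and rest epochs
#' (speeds near zero) so the movement filter and fast-lap rule both
#' have work to do. The polar angle integrates speed along the track
#' midline.
#'
#' @param track a [make_track()] geometry.
#' @param spec a [sim_session_spec()]; needs `duration_s >= 60`.
#' @param rest logical; set `FALSE` for a session with no rest epochs.
#' @param tracker_rate_factor tracker rate as a multiple of frame rate.
#' @return data frame of tracker samples: `time_s`, `angle_deg`,
#'   `x_mm`, `y_mm`, `speed_mm_s`, `heading_deg`.
#' @export
simulate_behavior <- function(track, spec, rest = TRUE,
                              tracker_rate_factor = 4) {
  if (spec$duration_s < 60) stop("duration_s must be >= 60")
  set.seed(spec$seed)
  fs <- spec$frame_rate_hz * tracker_rate_factor
  n <- ceiling(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # epoch schedule: normal runs 15-35 s around 110 mm/s, occasional
  # short sprint epochs above the 180 mm/s fast-lap threshold
  # (calibrated so roughly 7% of laps get removed), rests 2-6 s
  speed <- numeric(n)
  i <- 1
  while (i <= n) {
    if (runif(1) < 0.15) {
      run_len <- round(runif(1, 4, 6) * fs)
      v <- runif(1, 190, 240)
    } else {
      run_len <- round(runif(1, 15, 35) * fs)
      v <- exp(rnorm(1, log(110), 0.25))
    }
    hi <- min(n, i + run_len - 1)
    speed[i:hi] <- pmax(0, v + rnorm(hi - i + 1, 0, 8))
    i <- hi + 1
    if (rest && i <= n) {
      rest_len <- round(runif(1, 2, 6) * fs)
      hi <- min(n, i + rest_len - 1)
      speed[i:hi] <- pmax(0, rnorm(hi - i + 1, 2, 2))
      i <- hi + 1
    }
  }
  radius_mm <- (track$outer_diameter_mm + track$inner_diameter_mm) / 4
  omega <- speed / radius_mm            # rad/s along the midline
  angle <- cumsum(omega / fs)           # accumulated rotation, rad
  data.frame(
    time_s = t,
    angle_deg = (angle * 180 / pi) %% 360,
    x_mm = radius_mm * cos(angle),
    y_mm = radius_mm * sin(angle),
    speed_mm_s = speed,
    heading_deg = ((angle + pi / 2) * 180 / pi) %% 360
  )
}

# von Mises bump on the track with a given FWHM in cm, normalized to
# peak 1
vm_bump <- function(position_cm, center_cm, fwhm_cm, circumference_cm) {
  half_angle <- pi * fwhm_cm / circumference_cm
  kappa <- log(2) / (1 - cos(half_angle))
  theta <- 2 * pi * position_cm / circumference_cm
  mu <- 2 * pi * center_cm / circumference_cm
  exp(kappa * (cos(theta - mu) - 1))
}

#' Simulate a calcium population on top of a behavior session
#'
#' Place(-conjunctive) cells emit Poisson events at a rate peaked at
#' their field center with a von Mises tuning bump of the specified
#' FWHM; speed cells at a rate affine in running speed (half with
#' negative slope); untuned cells at a constant low rate. Fluorescence
#' traces are the AR(2)-kernel convolution of the event train, scaled
#' by `transient_amplitude`, riding on a baseline of 100, plus
#' `neuropil_gain` times a shared slow neuropil signal and Gaussian
#' frame noise.
#'
#' @param frames behavior frame table from [process_behavior()].
#' @param spec a [sim_session_spec()].
#' @param track a [make_track()] geometry.
#' @return list with `f_soma`, `f_neuropil` (cells x frames matrices)
#'   and `truth`: `cell_labels`, `field_centers_cm`, `field_fwhm_cm`,
#'   `speed_slopes`, `event_trains` (cells x frames event counts).
#' @export
simulate_population <- function(frames, spec, track) {
  stopifnot(inherits(spec, "sim_session_spec"))
  set.seed(spec$seed + 1L)
  nf <- nrow(frames)
  nc <- spec$n_cells
  dt <- 1 / spec$frame_rate_hz
  n_place <- round(spec$frac_place * nc)
  n_speed <- round(spec$frac_speed * nc)
  n_conj <- round(spec$frac_conjunctive * nc)
  if (n_place + n_speed + n_conj > nc)
    stop("category fractions must sum to at most 1")
  labels <- c(rep("place", n_place), rep("speed", n_speed),
              rep("conjunctive", n_conj),
              rep("none", nc - n_place - n_speed - n_conj))

  circ <- track$midline_circumference_cm
  centers <- rep(NA_real_, nc)
  slopes <- rep(NA_real_, nc)
  is_pl <- labels %in% c("place", "conjunctive")
  is_sp <- labels %in% c("speed", "conjunctive")
  centers[is_pl] <- runif(sum(is_pl), 0, circ)
  # affine speed gains: rate spans ~0.3..3 events/s over 0..150 mm/s
  sl <- runif(sum(is_sp), 0.012, 0.02)
  neg <- runif(sum(is_sp)) < 0.5
  slopes[is_sp] <- ifelse(neg, -sl, sl)

  g <- ar2_coefficients(spec$frame_rate_hz)
  # shared slow neuropil signal: low-pass white noise, sd 0.2 dF/F
  np_sig <- moving_average(rnorm(nf, 0, 1), round(spec$frame_rate_hz))
  np_sig <- np_sig / sd(np_sig) * 0.2

  baseline <- 100
  events <- matrix(0L, nc, nf)
  f_soma <- matrix(0, nc, nf)
  f_np <- matrix(0, nc, nf)
  base_rate <- 0.2
  peak_rate <- 2.5
  for (j in seq_len(nc)) {
    lambda <- rep(base_rate, nf)
    if (is_pl[j])
      lambda <- lambda + peak_rate *
        vm_bump(frames$position_cm, centers[j], spec$field_width_cm, circ) *
        as.numeric(frames$moving)
    if (is_sp[j]) {
      r <- 1 + slopes[j] * (frames$speed_mm_s - 100)
      lambda <- lambda + pmax(0, r)
    }
    ev <- rpois(nf, lambda * dt)
    events[j, ] <- ev
    c_t <- reconvolve_ar2(ev * spec$transient_amplitude, g)
    np_cell <- np_sig + rnorm(nf, 0, 0.02)
    f_soma[j, ] <- baseline * (1 + c_t + spec$neuropil_gain * np_sig) +
      rnorm(nf, 0, spec$noise_sd * baseline)
    f_np[j, ] <- baseline * (1 + np_cell)
  }
  list(f_soma = f_soma, f_neuropil = f_np,
       truth = list(cell_labels = labels, field_centers_cm = centers,
                    field_fwhm_cm = ifelse(is_pl, spec$field_width_cm, NA),
                    speed_slopes = slopes, event_trains = events))
}

#' Simulate a complete session (behavior + population)
#'
#' @param spec a [sim_session_spec()].
#' @param track a [make_track()] geometry (default [make_track()]).
#' @param rest passed to [simulate_behavior()].
#' @return list with `track`, `samples`, `frames`, `f_soma`,
#'   `f_neuropil`, `truth`.
#' @export
simulate_session <- function(spec = sim_session_spec(),
                             track = make_track(), rest = TRUE) {
  samples <- simulate_behavior(track, spec, rest = rest)
  frame_times <- seq(0, spec$duration_s - 1 / spec$frame_rate_hz,
                     by = 1 / spec$frame_rate_hz)
  frames <- process_behavior(samples, frame_times, track)
  pop <- simulate_population(frames, spec, track)
  c(list(track = track, samples = samples, frames = frames), pop)
}
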