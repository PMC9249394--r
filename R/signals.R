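# Calcium-trace post-processing: neuropil subtraction, dF/F with
# density-mode baseline, AR(2) sparse nonnegative deconvolution, QC.

#' Neuropil subtraction with correlation-minimizing coefficient
#'
#' Corrected fluorescence is
#' `F_corrected(n) = F_soma(n) - alpha * (F_neuropil(n) - mean(F_neuropil))`
#' with `alpha` chosen in `[0, 1]` to minimize the absolute Pearson
#' correlation between the corrected trace and the neuropil trace.
#'
#' @param f_soma somatic ROI fluorescence trace.
#' @param f_neuropil matched neuropil trace (same length).
#' @param grid_n resolution of the initial alpha grid search.
#' @return list with `f_corrected`, `alpha`, and `degenerate` (TRUE if
#'   the corrected trace is nearly constant at the optimum, as when the
#'   soma trace is itself the neuropil signal).
#' @export
subtract_neuropil <- function(f_soma, f_neuropil, grid_n = 101) {
  stopifnot(length(f_soma) == length(f_neuropil), length(f_soma) >= 100)
  if (sd(f_neuropil) == 0) stop("neuropil trace is constant; correlation undefined")
  np_c <- f_neuropil - mean(f_neuropil)
  objective <- function(a) {
    fc <- f_soma - a * np_c
    if (sd(fc) < .Machine$double.eps * (abs(mean(fc)) + 1)) return(0)
    abs(cor(fc, f_neuropil))
  }
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, objective, numeric(1))
  a0 <- grid[which.min(vals)]
  lo <- max(0, a0 - 1 / (grid_n - 1)); hi <- min(1, a0 + 1 / (grid_n - 1))
  opt <- optimize(objective, c(lo, hi))
  alpha <- if (opt$objective < min(vals)) opt$minimum else a0
  fc <- f_soma - alpha * np_c
  degenerate <- sd(fc) < 1e-8 * sd(f_soma)
  list(f_corrected = fc, alpha = alpha, degenerate = degenerate)
}

#' dF/F with first-mode baseline
#'
#' The baseline `F0` is the location of the first (lowest-fluorescence)
#' mode of a Gaussian kernel-density estimate of the corrected trace;
#' active cells spend most frames near baseline, so the lowest density
#' mode tracks resting fluorescence even with frequent transients.
#'
#' @param f_corrected corrected fluorescence trace (>= 100 frames).
#' @return list with `dff` and `f0`. If `F0 <= 0` the dF/F is undefined:
#'   `dff` is all-`NA` and `baseline_valid` is `FALSE`.
#' @export
compute_dff <- function(f_corrected) {
  stopifnot(length(f_corrected) >= 100, all(is.finite(f_corrected)))
  if (sd(f_corrected) == 0) {
    f0 <- f_corrected[1]
  } else {
    d <- density(f_corrected, bw = "nrd0")
    # local maxima of the KDE; "first" = lowest fluorescence value
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1
    if (length(is_max) == 0) is_max <- which.max(y)
    f0 <- d$x[min(is_max)]
  }
  if (!is.finite(f0) || f0 <= 0) {
    return(list(dff = rep(NA_real_, length(f_corrected)), f0 = f0,
                baseline_valid = FALSE))
  }
  list(dff = (f_corrected - f0) / f0, f0 = f0, baseline_valid = TRUE)
}

#' AR(2) coefficients from rise and decay time constants
#'
#' The calcium impulse response is modeled as a difference of
#' exponentials (rise ~0.1 s, decay ~1.5 s for a slow sensor),
#' equivalent to an AR(2) process with poles `exp(-dt/tau)`.
#'
#' @param frame_rate_hz sampling rate (Hz).
#' @param tau_decay_s,tau_rise_s time constants (s).
#' @return numeric `c(g1, g2)` with `g1 = d + r`, `g2 = -d*r`.
#' @export
ar2_coefficients <- function(frame_rate_hz, tau_decay_s = 1.5,
                             tau_rise_s = 0.1) {
  stopifnot(frame_rate_hz > 0, tau_decay_s > tau_rise_s, tau_rise_s > 0)
  d <- exp(-1 / (frame_rate_hz * tau_decay_s))
  r <- exp(-1 / (frame_rate_hz * tau_rise_s))
  c(d + r, -d * r)
}

# impulse response of the AR(2) kernel, length n
ar2_kernel <- function(g, n) {
  as.numeric(stats::filter(c(1, rep(0, n - 1)), g, method = "recursive"))
}

#' Sparse nonnegative AR(2) deconvolution
#'
#' Estimates a nonnegative event train `s` such that the AR(2)
#' reconvolution approximates the dF/F trace. The AR model is first
#' inverted exactly (`s(n) = y(n) - g1*y(n-1) - g2*y(n-2)`), then
#' negative innovations are clamped and sub-threshold innovations are
#' zeroed, with the sparsity threshold tied to a median-absolute-
#' deviation noise estimate of the innovation series. On noiseless
#' kernel superpositions the recovery is exact.
#'
#' @param dff dF/F trace (finite).
#' @param frame_rate_hz sampling rate (Hz).
#' @param g optional AR(2) coefficients; default from
#'   [ar2_coefficients()] at the given frame rate.
#' @param sparsity_nsd threshold in units of the MAD noise sd.
#' @return nonnegative event-amplitude series, same length as `dff`.
#' @export
infer_spike_rate <- function(dff, frame_rate_hz, g = NULL, sparsity_nsd = 3) {
  if (!all(is.finite(dff))) stop("dff must be finite")
  stopifnot(frame_rate_hz > 0)
  g <- g %||% ar2_coefficients(frame_rate_hz)
  n <- length(dff)
  if (n < 3) return(pmax(dff, 0))
  s <- dff
  s[2] <- dff[2] - g[1] * dff[1]
  idx <- 3:n
  s[idx] <- dff[idx] - g[1] * dff[idx - 1] - g[2] * dff[idx - 2]
  # noise estimated from negative innovations only: the noise is
  # symmetric while true events are strictly positive, so the MAD of
  # the full series inflates on densely firing cells
  neg <- s[s < 0]
  noise_sd <- if (length(neg) > 10) median(abs(neg)) / 0.6744898
              else mad(s, center = 0)
  # absolute floor guards against floating-point dust on noiseless input
  thr <- max(sparsity_nsd * noise_sd, 1e-9 * max(abs(dff), 1))
  s[s < thr] <- 0
  pmax(s, 0)
}

# reconvolve an event train through the AR(2) kernel
reconvolve_ar2 <- function(s, g) {
  as.numeric(stats::filter(s, g, method = "recursive"))
}

#' Advisory QC flags from mean event rate
#'
#' Cells whose mean inferred event rate during moving frames is above
#' 10/s or below 1/s are flagged for review; flags are advisory and do
#' not themselves exclude cells.
#'
#' @param rates nonnegative event-amplitude series.
#' @param moving_mask logical mask aligned to `rates`.
#' @param frame_rate_hz sampling rate (Hz).
#' @param high,low rate thresholds in events/s.
#' @return one of `"ok"`, `"high_rate"`, `"low_rate"`, `"undetermined"`.
#' @export
qc_rate_flags <- function(rates, moving_mask, frame_rate_hz,
                          high = 10, low = 1) {
  stopifnot(length(rates) == length(moving_mask))
  if (!any(moving_mask)) return("undetermined")
  # event amplitudes are treated as (fractional) spike counts per frame
  r <- sum(rates[moving_mask]) / (sum(moving_mask) / frame_rate_hz)
  if (r > high) "high_rate" else if (r < low) "low_rate" else "ok"
}

#' Full trace post-processing for one cell
#'
#' Chains [subtract_neuropil()], [compute_dff()] and
#' [infer_spike_rate()].
#'
#' @inheritParams subtract_neuropil
#' @inheritParams infer_spike_rate
#' @return list with `alpha`, `f0`, `dff`, `rates`, `baseline_valid`.
#' @export
process_trace <- function(f_soma, f_neuropil, frame_rate_hz, g = NULL) {
  sub <- subtract_neuropil(f_soma, f_neuropil)
  base <- compute_dff(sub$f_corrected)
  rates <- if (base$baseline_valid)
    infer_spike_rate(base$dff, frame_rate_hz, g = g)
  else rep(NA_real_, length(f_soma))
  list(alpha = sub$alpha, f0 = base$f0, dff = base$dff, rates = rates,
       baseline_valid = base$baseline_valid)
}
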