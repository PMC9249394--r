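# Cell placement along the DG-to-CA1 transverse axis and tests for
# non-uniform spatial information along it.

rotate_xy <- function(xy, theta_deg) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy %*% R
}

#' Fit the cell-body-layer curve by rotation search
#'
#' For each rotation of the field of view on a grid over [0, 180), the
#' centroids are rotated and a parabola `y = a*(x - b)^2 + c` fit by
#' least squares; the rotation maximizing R^2 is kept. The inflection
#' point (the bend of the layer) is the parabola vertex `(b, c)`
#' de-rotated to the original coordinates.
#'
#' @param centroids_px n x 2 matrix / data frame of (x, y) centroids.
#' @param rotation_step_deg grid step (degrees).
#' @return list of class `axis_geometry`: `rotation_deg`, `parabola`
#'   (a, b, c in rotated coordinates), `inflection_xy_px`, `fit_r2`.
#' @export
fit_axis_curve <- function(centroids_px, rotation_step_deg = 1) {
  xy <- as.matrix(centroids_px)[, 1:2, drop = FALSE]
  if (nrow(xy) < 20) stop("need at least 20 centroids")
  best <- list(r2 = -Inf)
  for (th in seq(0, 180 - rotation_step_deg, by = rotation_step_deg)) {
    r <- rotate_xy(xy, th)
    x <- r[, 1]; y <- r[, 2]
    if (sd(x) < 1e-9) next
    fit <- lm(y ~ x + I(x^2))
    co <- coef(fit)
    if (!is.finite(co[3]) || abs(co[3]) < 1e-12) next
    tss <- sum((y - mean(y))^2)
    if (tss == 0) next
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > best$r2) {
      a <- co[3]; b <- -co[2] / (2 * a); c <- co[1] - a * b^2
      best <- list(r2 = r2, theta = th, a = unname(a), b = unname(b),
                   c = unname(c))
    }
  }
  if (!is.finite(best$r2)) stop("degenerate centroid configuration")
  infl_rot <- c(best$b, best$c)
  infl <- rotate_xy(matrix(infl_rot, 1, 2), -best$theta)[1, ]
  structure(list(rotation_deg = best$theta,
                 parabola = c(a = best$a, b = best$b, c = best$c),
                 inflection_xy_px = infl, fit_r2 = best$r2),
            class = "axis_geometry")
}

# arc length of y = a(x-b)^2 + c from b to x (signed by x - b)
parabola_arc_length <- function(a, b, x) {
  u <- 2 * a * (x - b)
  # integral of sqrt(1 + (2a t)^2) dt from 0 to x-b, closed form
  (u * sqrt(1 + u^2) + asinh(u)) / (4 * a)
}

#' Signed arc distance of a cell from the inflection point
#'
#' The nearest point on the fitted parabola to the centroid is located
#' numerically; the distance is the arc length along the curve from
#' the inflection (vertex) to that point, signed by the direction of
#' increasing x in rotated coordinates.
#'
#' @param geometry an `axis_geometry` from [fit_axis_curve()].
#' @param centroid_px length-2 (x, y) or n x 2 matrix.
#' @param um_per_px scale (um per pixel).
#' @return signed distance(s) in um.
#' @export
cell_axis_distance <- function(geometry, centroid_px, um_per_px = 1) {
  xy <- matrix(as.numeric(as.matrix(centroid_px)), ncol = 2)
  a <- geometry$parabola["a"]; b <- geometry$parabola["b"]
  cc <- geometry$parabola["c"]
  r <- rotate_xy(xy, geometry$rotation_deg)
  vapply(seq_len(nrow(r)), function(i) {
    px <- r[i, 1]; py <- r[i, 2]
    d2 <- function(x) (x - px)^2 + (a * (x - b)^2 + cc - py)^2
    span <- max(abs(px - b), 10 / um_per_px, 1) * 2 + 10
    opt <- optimize(d2, c(b - span, b + span))
    xn <- opt$minimum
    s <- parabola_arc_length(a, b, xn)
    unname(s * um_per_px)
  }, numeric(1))
}

#' Sliding-window spatial-information profile along the axis
#'
#' Mean SI in windows of `window_um` stepped by `step_um` across
#' [-range_um, range_um], with a bootstrap s.e.m. (cells resampled
#' with replacement) and a shuffle control that permutes SI values
#' across cells while keeping positions; windows whose mean falls
#' outside the shuffle 2.5-97.5 percentile envelope are flagged.
#'
#' @param distances_um signed axis distances per cell.
#' @param si_values spatial information per cell.
#' @param window_um,step_um window width and step (um).
#' @param n_boot,n_shuffle resampling iterations.
#' @param range_um cells beyond +/- this distance are excluded.
#' @param seed integer seed.
#' @return data frame (`axis_profile`): `center_um`, `mean_si`,
#'   `boot_sem`, `n_cells`, `shuffle_lo`, `shuffle_hi`, `flagged`.
#' @export
sliding_window_profile <- function(distances_um, si_values,
                                   window_um = 200, step_um = 50,
                                   n_boot = 1000, n_shuffle = 1000,
                                   range_um = 600, seed = 1) {
  keep <- is.finite(distances_um) & is.finite(si_values) &
    abs(distances_um) <= range_um
  d <- distances_um[keep]; si <- si_values[keep]
  if (length(d) < 50) stop("need at least 50 cells within range")
  set.seed(seed)
  centers <- seq(-range_um + window_um / 2, range_um - window_um / 2,
                 by = step_um)
  nw <- length(centers)
  mean_si <- boot_sem <- lo <- hi <- rep(NA_real_, nw)
  ncell <- integer(nw)
  win_idx <- lapply(centers, function(cc)
    which(d >= cc - window_um / 2 & d < cc + window_um / 2))
  for (w in seq_len(nw)) {
    ii <- win_idx[[w]]
    ncell[w] <- length(ii)
    if (length(ii) == 0) next
    mean_si[w] <- mean(si[ii])
    bs <- vapply(seq_len(n_boot), function(k)
      mean(si[sample(ii, length(ii), replace = TRUE)]), numeric(1))
    boot_sem[w] <- sd(bs)
  }
  shuf_means <- matrix(NA_real_, n_shuffle, nw)
  for (k in seq_len(n_shuffle)) {
    sp <- sample(si)
    shuf_means[k, ] <- vapply(win_idx, function(ii)
      if (length(ii)) mean(sp[ii]) else NA_real_, numeric(1))
  }
  for (w in seq_len(nw)) {
    if (ncell[w] == 0) next
    lo[w] <- quantile(shuf_means[, w], 0.025, na.rm = TRUE, names = FALSE)
    hi[w] <- quantile(shuf_means[, w], 0.975, na.rm = TRUE, names = FALSE)
  }
  out <- data.frame(center_um = centers, mean_si = mean_si,
                    boot_sem = boot_sem, n_cells = ncell,
                    shuffle_lo = lo, shuffle_hi = hi,
                    flagged = !is.na(mean_si) &
                      (mean_si < lo | mean_si > hi))
  class(out) <- c("axis_profile", class(out))
  out
}

#' General linear F-test of SI flatness along the axis
#'
#' Full model: per-bin means over `n_bins` equal-width distance bins
#' in [-range_um, range_um]; reduced model: the grand mean.
#' `F = ((RSS_r - RSS_f)/(n_bins - 1)) / (RSS_f/(N - n_bins))` with
#' `df1 = n_bins - 1`, `df2 = N - n_bins` (a one-way ANOVA F on the
#' binned positions).
#'
#' @param distances_um signed axis distances per cell.
#' @param si_values spatial information per cell.
#' @param n_bins number of distance bins.
#' @param range_um analysis range (cells outside excluded).
#' @return list `f_stat`, `df1`, `df2`, `p`.
#' @export
flat_f_test <- function(distances_um, si_values, n_bins = 5,
                        range_um = 600) {
  keep <- is.finite(distances_um) & is.finite(si_values) &
    abs(distances_um) <= range_um
  d <- distances_um[keep]; si <- si_values[keep]
  edges <- seq(-range_um, range_um, length.out = n_bins + 1)
  bin <- cut(d, edges, include.lowest = TRUE)
  if (any(table(bin) == 0)) stop("empty distance bin; adjust n_bins/range")
  n <- length(si)
  rss_r <- sum((si - mean(si))^2)
  bin_means <- tapply(si, bin, mean)
  rss_f <- sum((si - bin_means[bin])^2)
  df1 <- n_bins - 1; df2 <- n - n_bins
  if (rss_f == 0) {
    # all values equal: no evidence either way; otherwise the full
    # model is exact and the flat model is rejected outright
    if (rss_r <= .Machine$double.eps * n)
      return(list(f_stat = 0, df1 = df1, df2 = df2, p = 1))
    return(list(f_stat = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(f_stat = f, df1 = df1, df2 = df2, p = pf(f, df1, df2,
                                                lower.tail = FALSE))
}

#' Simulate cell centroids along a rotated layer curve
#'
#' Centroids are scattered (Gaussian jitter) around the rotated curve
#' `y = a*(x - b)^2 + c`; per-cell SI values are drawn from
#' `si_profile` (a function of true signed arc distance from the
#' inflection, um) plus Gaussian noise.
#'
#' @param a,b,c parabola parameters in unrotated frame (px).
#' @param rotation_deg rotation applied to the curve.
#' @param n_cells number of cells (>= 20).
#' @param x_range_px range of x (unrotated) over which cells spread.
#' @param jitter_px isotropic centroid jitter sd (px).
#' @param si_profile function(distance_um) -> mean SI.
#' @param si_noise_sd sd of SI noise.
#' @param um_per_px scale.
#' @param seed integer seed.
#' @return list with `centroids_px` (n x 2), `si`, `true_distance_um`.
#' @export
simulate_axis_cells <- function(a = 0.002, b = 250, c = 100,
                                rotation_deg = 30, n_cells = 300,
                                x_range_px = c(-300, 300),
                                jitter_px = 4,
                                si_profile = function(d) 0.5 + 0 * d,
                                si_noise_sd = 0.15, um_per_px = 1.09,
                                seed = 1) {
  stopifnot(n_cells >= 20)
  set.seed(seed)
  x <- runif(n_cells, b + x_range_px[1], b + x_range_px[2])
  y <- a * (x - b)^2 + c
  s_um <- parabola_arc_length(a, b, x) * um_per_px
  xy <- cbind(x, y) + matrix(rnorm(2 * n_cells, 0, jitter_px), ncol = 2)
  xy <- rotate_xy(xy, -rotation_deg)
  si <- si_profile(s_um) + rnorm(n_cells, 0, si_noise_sd)
  list(centroids_px = xy, si = si, true_distance_um = s_um)
}
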