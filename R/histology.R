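# Glial-cell density versus distance from the implant face, with a
# mirrored contralateral control and bootstrap uncertainty.

#' Minimal Euclidean distance from centroids to a face segment
#'
#' @param centroids_xy n x 2 matrix of (x, y) centroid coordinates (um).
#' @param face_line length-4 vector `c(x1, y1, x2, y2)` defining the
#'   implant-face segment.
#' @return numeric vector of distances (um).
#' @export
distance_to_face <- function(centroids_xy, face_line) {
  xy <- matrix(as.numeric(as.matrix(centroids_xy)), ncol = 2)
  stopifnot(all(is.finite(xy)), length(face_line) == 4)
  p1 <- face_line[1:2]; p2 <- face_line[3:4]
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) return(sqrt(rowSums(sweep(xy, 2, p1)^2)))
  tt <- pmin(pmax(((xy[, 1] - p1[1]) * v[1] + (xy[, 2] - p1[2]) * v[2]) / L2,
                  0), 1)
  px <- p1[1] + tt * v[1]; py <- p1[2] + tt * v[2]
  sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
}

#' Percent change of glial density in distance bins, with bootstrap
#'
#' Both distance sets are binned at `bin_um`; per bin the percent
#' change is `(implant - control) / control * 100`. The bootstrap
#' resamples each whole distance vector with replacement `n_boot`
#' times to give per-bin confidence intervals.
#'
#' @param dist_implant,dist_control distances (um) on each side.
#' @param bin_um bin width (um).
#' @param n_boot bootstrap resamples.
#' @param max_um outer edge of the last bin (default covers the data).
#' @param seed integer seed.
#' @return data frame (`density_profile`): `bin_lo_um`, `bin_hi_um`,
#'   `count_implant`, `count_control`, `percent_change`, `boot_lo`,
#'   `boot_hi` (95% CI; `NA` where the control bin is empty).
#' @export
density_percent_change <- function(dist_implant, dist_control,
                                   bin_um = 50, n_boot = 1000,
                                   max_um = NULL, seed = 1) {
  stopifnot(length(dist_implant) > 0, length(dist_control) > 0)
  set.seed(seed)
  max_um <- max_um %||% (ceiling(max(c(dist_implant, dist_control)) /
                                   bin_um) * bin_um)
  edges <- seq(0, max_um, by = bin_um)
  nb <- length(edges) - 1
  binc <- function(d) tabulate(findInterval(d, edges,
                                            rightmost.closed = TRUE),
                               nbins = nb)
  ci <- binc(dist_implant); cc <- binc(dist_control)
  pc <- ifelse(cc > 0, (ci - cc) / cc * 100, NA_real_)
  boots <- matrix(NA_real_, n_boot, nb)
  for (k in seq_len(n_boot)) {
    bi <- binc(sample(dist_implant, replace = TRUE))
    bc <- binc(sample(dist_control, replace = TRUE))
    boots[k, ] <- ifelse(bc > 0, (bi - bc) / bc * 100, NA_real_)
  }
  lo <- apply(boots, 2, quantile, 0.025, na.rm = TRUE, names = FALSE)
  hi <- apply(boots, 2, quantile, 0.975, na.rm = TRUE, names = FALSE)
  out <- data.frame(bin_lo_um = edges[-length(edges)], bin_hi_um = edges[-1],
                    count_implant = ci, count_control = cc,
                    percent_change = pc, boot_lo = lo, boot_hi = hi)
  class(out) <- c("density_profile", class(out))
  out
}
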