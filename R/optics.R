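# PSF characterization from fluorescent bead stacks and the
# theoretical two-photon resolution model.

#' Specification for a synthetic bead stack
#'
#' Sub-resolution fluorescent beads rendered as 3-D Gaussians of known
#' FWHM (`FWHM = 2*sqrt(2*ln 2)*sigma`) at recorded sub-voxel
#' centroids. Defaults emulate a typical bead-calibration acquisition:
#' 0.07 um lateral pixels and 0.5 um z-planes.
#'
#' @param stack_shape_px integer 3-vector (Z, Y, X).
#' @param xy_um_per_px,z_um_per_plane voxel scales (um).
#' @param psf_fwhm_xy_um,psf_fwhm_z_um generating FWHMs (um).
#' @param n_beads number of beads.
#' @param min_separation_px minimal pairwise center distance (px).
#' @param amplitude peak intensity per bead.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @param allow_edge if TRUE beads may touch the first/last plane.
#' @param seed integer seed.
#' @return a `sim_bead_spec` list.
#' @export
sim_bead_spec <- function(stack_shape_px = c(40, 128, 128),
                          xy_um_per_px = 0.07, z_um_per_plane = 0.5,
                          psf_fwhm_xy_um = 0.6, psf_fwhm_z_um = 3.4,
                          n_beads = 12, min_separation_px = 25,
                          amplitude = 100, noise_sd = 0,
                          allow_edge = FALSE, seed = 1) {
  stopifnot(psf_fwhm_xy_um > 0, psf_fwhm_z_um > 0, xy_um_per_px > 0,
            z_um_per_plane > 0, n_beads >= 1)
  structure(as.list(environment()), class = "sim_bead_spec")
}

#' Simulate a 3-D bead stack
#'
#' @param spec a [sim_bead_spec()].
#' @return list with `stack` (Z x Y x X array) and `truth` data frame
#'   of sub-voxel centroids (`z`, `y`, `x`, 1-based voxel coordinates).
#' @export
simulate_bead_stack <- function(spec) {
  stopifnot(inherits(spec, "sim_bead_spec"))
  set.seed(spec$seed)
  dims <- spec$stack_shape_px
  sz <- spec$psf_fwhm_z_um / (2 * sqrt(2 * log(2))) / spec$z_um_per_plane
  sxy <- spec$psf_fwhm_xy_um / (2 * sqrt(2 * log(2))) / spec$xy_um_per_px
  mz <- if (spec$allow_edge) 0 else ceiling(4 * sz)
  mxy <- ceiling(4 * sxy) + 1
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(centers) < spec$n_beads) {
    tries <- tries + 1
    if (tries > 20000)
      stop("cannot place ", spec$n_beads,
           " beads at min_separation ", spec$min_separation_px, " px")
    cand <- c(runif(1, 1 + mz, dims[1] - mz),
              runif(1, 1 + mxy, dims[2] - mxy),
              runif(1, 1 + mxy, dims[3] - mxy))
    if (nrow(centers) > 0) {
      d <- sqrt(rowSums(sweep(centers, 2, cand)^2))
      if (any(d < spec$min_separation_px)) next
    }
    centers <- rbind(centers, cand)
  }
  stack <- array(0, dims)
  zg <- seq_len(dims[1]); yg <- seq_len(dims[2]); xg <- seq_len(dims[3])
  for (b in seq_len(nrow(centers))) {
    cz <- centers[b, 1]; cy <- centers[b, 2]; cx <- centers[b, 3]
    zi <- zg[abs(zg - cz) <= 5 * sz + 1]
    yi <- yg[abs(yg - cy) <= 5 * sxy + 1]
    xi <- xg[abs(xg - cx) <= 5 * sxy + 1]
    gz <- exp(-(zi - cz)^2 / (2 * sz^2))
    gy <- exp(-(yi - cy)^2 / (2 * sxy^2))
    gx <- exp(-(xi - cx)^2 / (2 * sxy^2))
    stack[zi, yi, xi] <- stack[zi, yi, xi] +
      spec$amplitude * outer(gz, outer(gy, gx))
  }
  if (spec$noise_sd > 0)
    stack <- stack + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
  colnames(centers) <- c("z", "y", "x")
  list(stack = stack, truth = as.data.frame(centers))
}

# 3-D component labeling: 2-D labeling per z-slice, then union-find
# merging of labels that overlap between adjacent slices
label_components_3d <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  offset <- 0L
  for (z in seq_len(dims[1])) {
    sl <- EBImage::bwlabel(matrix(mask[z, , ], dims[2], dims[3]))
    sl <- matrix(as.integer(sl), dims[2], dims[3])
    sl[sl > 0] <- sl[sl > 0] + offset
    offset <- max(offset, max(sl))
    lab[z, , ] <- sl
  }
  if (offset == 0) return(lab)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (z in seq_len(dims[1] - 1)) {
    a <- lab[z, , ]; b <- lab[z + 1, , ]
    both <- a > 0 & b > 0
    if (!any(both)) next
    prs <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(prs))) {
      ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  nz <- lab > 0
  lab[nz] <- dense[lab[nz]]
  lab
}

#' Detect isolated, fully contained beads in a z-stack
#'
#' Candidate beads are supra-threshold connected components. A bead is
#' excluded if any neighbor bead center is closer than
#' `min_separation_px` or if its component touches the first or last
#' z-plane (not fully contained).
#'
#' @param stack 3-D array (Z, Y, X), nonnegative.
#' @param min_separation_px isolation radius (px).
#' @param require_contained exclude beads touching the z boundaries.
#' @param threshold intensity threshold; default `median + 5 * mad`
#'   with a floor at 10% of the dynamic range.
#' @param min_voxels smallest component treated as a bead candidate
#'   (suppresses single-voxel noise excursions).
#' @return data frame of centroids (`z`, `y`, `x`, intensity-weighted,
#'   1-based voxel coordinates); zero rows when nothing survives.
#' @export
detect_beads <- function(stack, min_separation_px = 25,
                         require_contained = TRUE, threshold = NULL,
                         min_voxels = 8) {
  if (length(stack) == 0) stop("empty stack")
  stopifnot(length(dim(stack)) == 3)
  if (is.null(threshold)) {
    # robust noise floor plus a relative floor at 10% of the dynamic
    # range (the noise estimate alone underflows on noiseless stacks)
    threshold <- max(median(stack) + 5 * mad(stack),
                     min(stack) + 0.1 * diff(range(stack)))
  }
  lab <- label_components_3d(stack > threshold)
  nl <- max(lab)
  if (nl == 0) return(data.frame(z = numeric(0), y = numeric(0),
                                 x = numeric(0)))
  sizes <- tabulate(lab[lab > 0], nbins = nl)
  ids <- which(sizes >= min_voxels)
  if (length(ids) == 0) return(data.frame(z = numeric(0), y = numeric(0),
                                          x = numeric(0)))
  dims <- dim(stack)
  nl <- length(ids)
  cent <- matrix(NA_real_, nl, 3)
  touches <- logical(nl)
  for (k in seq_len(nl)) {
    vi <- which(lab == ids[k])
    co <- arrayInd(vi, dims)
    w <- stack[vi]
    cent[k, ] <- colSums(co * w) / sum(w)
    touches[k] <- any(co[, 1] == 1 | co[, 1] == dims[1])
  }
  keep <- rep(TRUE, nl)
  if (require_contained) keep <- keep & !touches
  if (nl > 1) {
    dmat <- as.matrix(dist(cent))
    diag(dmat) <- Inf
    keep <- keep & (apply(dmat, 1, min) >= min_separation_px)
  }
  out <- as.data.frame(cent[keep, , drop = FALSE])
  names(out) <- c("z", "y", "x")
  out
}

# trilinear interpolation of stack at (z,y,x) offsets around a center
extract_window_3d <- function(stack, center, half_z, half_xy) {
  dims <- dim(stack)
  zo <- seq(-half_z, half_z); yo <- seq(-half_xy, half_xy)
  xo <- seq(-half_xy, half_xy)
  out <- array(NA_real_, c(length(zo), length(yo), length(xo)))
  for (iz in seq_along(zo)) for (iy in seq_along(yo)) {
    z <- center[1] + zo[iz]; y <- center[2] + yo[iy]
    x <- center[3] + xo
    z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
    fz <- z - z0; fy <- y - y0; fx <- x - x0
    if (z0 < 1 || z0 + 1 > dims[1] || y0 < 1 || y0 + 1 > dims[2]) next
    okx <- x0 >= 1 & x0 + 1 <= dims[3]
    v <- rep(NA_real_, length(xo))
    if (any(okx)) {
      xi <- x0[okx]
      c00 <- stack[z0, y0, xi] * (1 - fx[okx]) + stack[z0, y0, xi + 1] * fx[okx]
      c01 <- stack[z0, y0 + 1, xi] * (1 - fx[okx]) + stack[z0, y0 + 1, xi + 1] * fx[okx]
      c10 <- stack[z0 + 1, y0, xi] * (1 - fx[okx]) + stack[z0 + 1, y0, xi + 1] * fx[okx]
      c11 <- stack[z0 + 1, y0 + 1, xi] * (1 - fx[okx]) + stack[z0 + 1, y0 + 1, xi + 1] * fx[okx]
      v[okx] <- (c00 * (1 - fy) + c01 * fy) * (1 - fz) +
        (c10 * (1 - fy) + c11 * fy) * fz
    }
    out[iz, iy, ] <- v
  }
  out
}

#' FWHM of a 1-D profile by linear interpolation at half maximum
#'
#' The profile background (median of its border samples) is subtracted
#' before measuring; the crossing points on each side of the maximum
#' are located by linear interpolation.
#'
#' @param profile numeric vector.
#' @param spacing physical spacing between samples.
#' @return FWHM in the units of `spacing`, or `NA` if no crossing.
#' @export
fwhm_of_profile <- function(profile, spacing = 1) {
  p <- profile[is.finite(profile)]
  if (length(p) < 5) return(NA_real_)
  nb <- max(1, round(length(p) * 0.1))
  bg <- median(c(head(p, nb), tail(p, nb)))
  p <- p - bg
  imax <- which.max(p)
  half <- p[imax] / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(imax, 2)) if (p[i - 1] <= half && p[i] > half) {
    left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break
  }
  for (i in seq(imax, length(p) - 1)) if (p[i + 1] <= half && p[i] > half) {
    right <- i + (p[i] - half) / (p[i] - p[i + 1]); break
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * spacing
}

#' Measure the PSF from detected beads
#'
#' Each bead is sub-pixel registered at its centroid (trilinear
#' resampling), the XY plane and XZ slice through the centroid are
#' averaged across beads, and the FWHM of the central row/column of
#' the averaged profiles gives the lateral and axial resolution.
#'
#' @param stack 3-D array (Z, Y, X).
#' @param centroids data frame from [detect_beads()].
#' @param xy_um_per_px,z_um_per_plane voxel scales (um).
#' @param half_xy,half_z window half-sizes (px / planes).
#' @return list of class `bead_profile`: `fwhm_lateral_um`,
#'   `fwhm_axial_um`, `xy_profile`, `xz_profile`, `n_beads`.
#' @export
measure_psf <- function(stack, centroids, xy_um_per_px = 0.07,
                        z_um_per_plane = 0.5, half_xy = 12, half_z = 8) {
  stopifnot(nrow(centroids) >= 1)
  dims <- dim(stack)
  if (any(centroids$z < 1 | centroids$z > dims[1] |
          centroids$y < 1 | centroids$y > dims[2] |
          centroids$x < 1 | centroids$x > dims[3]))
    stop("centroid outside stack")
  nxy <- 2 * half_xy + 1; nz <- 2 * half_z + 1
  xy_sum <- matrix(0, nxy, nxy); xz_sum <- matrix(0, nz, nxy)
  xy_n <- matrix(0, nxy, nxy); xz_n <- matrix(0, nz, nxy)
  for (b in seq_len(nrow(centroids))) {
    ctr <- as.numeric(centroids[b, c("z", "y", "x")])
    w <- extract_window_3d(stack, ctr, half_z, half_xy)
    peak <- max(w, na.rm = TRUE)
    if (!is.finite(peak) || peak <= 0) next
    w <- w / peak                       # scale invariance across beads
    xyp <- w[half_z + 1, , ]
    xzp <- w[, half_xy + 1, ]
    ok <- is.finite(xyp); xy_sum[ok] <- xy_sum[ok] + xyp[ok]; xy_n <- xy_n + ok
    ok <- is.finite(xzp); xz_sum[ok] <- xz_sum[ok] + xzp[ok]; xz_n <- xz_n + ok
  }
  xy_prof <- xy_sum / pmax(xy_n, 1)
  xz_prof <- xz_sum / pmax(xz_n, 1)
  f_row <- fwhm_of_profile(xy_prof[half_xy + 1, ], xy_um_per_px)
  f_col <- fwhm_of_profile(xy_prof[, half_xy + 1], xy_um_per_px)
  fwhm_lat <- mean(c(f_row, f_col), na.rm = TRUE)
  fwhm_ax <- fwhm_of_profile(xz_prof[, half_xy + 1], z_um_per_plane)
  structure(list(fwhm_lateral_um = fwhm_lat, fwhm_axial_um = fwhm_ax,
                 xy_profile = xy_prof, xz_profile = xz_prof,
                 n_beads = nrow(centroids)),
            class = "bead_profile")
}

#' Theoretical two-photon resolution from wavelength and NA
#'
#' 1/e half-widths of the two-photon excitation PSF:
#' `w_xy = 0.320*lambda/(sqrt(2)*NA)` for NA <= 0.7, else
#' `0.325*lambda/(sqrt(2)*NA^0.91)`;
#' `w_z = (0.532*lambda/sqrt(2)) * 1/(n - sqrt(n^2 - NA^2))`.
#' FWHMs are `w * 2*sqrt(ln 2)`.
#'
#' @param wavelength_um excitation wavelength (um).
#' @param na numerical aperture (0 < NA < n).
#' @param n immersion refractive index.
#' @return list of class `optical_model`: `omega_xy_um`, `omega_z_um`,
#'   `fwhm_xy_um`, `fwhm_z_um` plus the inputs.
#' @export
theoretical_resolution <- function(wavelength_um, na, n = 1.33) {
  if (!(na > 0 && na < n)) stop("requires 0 < NA < n")
  stopifnot(wavelength_um > 0)
  w_xy <- if (na <= 0.7) 0.320 * wavelength_um / (sqrt(2) * na)
          else 0.325 * wavelength_um / (sqrt(2) * na^0.91)
  w_z <- (0.532 * wavelength_um / sqrt(2)) * (1 / (n - sqrt(n^2 - na^2)))
  k <- 2 * sqrt(log(2))
  structure(list(wavelength_um = wavelength_um, numerical_aperture = na,
                 refractive_index = n, omega_xy_um = w_xy,
                 omega_z_um = w_z, fwhm_xy_um = k * w_xy,
                 fwhm_z_um = k * w_z),
            class = "optical_model")
}

#' Effective NA of a periscope prism from beam-clipping geometry
#'
#' The imaging-face aperture limits the half-angle of the focusing
#' cone through the glass path; with the photon invariant
#' `n*sin(theta)` the effective NA is
#' `min(n_glass * sin(atan((aperture/2)/glass_path)), objective cap)`.
#'
#' @param aperture_mm imaging-face width (mm).
#' @param glass_path_mm longest path through glass (mm).
#' @param n_glass refractive index of the glass.
#' @param objective_na_cap NA of the objective (upper bound).
#' @return effective numerical aperture (dimensionless).
#' @export
effective_na <- function(aperture_mm, glass_path_mm, n_glass = 1.5,
                         objective_na_cap = 0.8) {
  stopifnot(aperture_mm > 0, glass_path_mm > 0, n_glass > 0,
            objective_na_cap > 0)
  min(n_glass * sin(atan((aperture_mm / 2) / glass_path_mm)),
      objective_na_cap)
}
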