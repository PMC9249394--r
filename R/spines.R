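# Dendritic spine extraction, morphometric classification, density,
# cross-day matching, turnover and survival statistics.

# ---- image helpers --------------------------------------------------

# integer translation shift of a matrix, zero-filled
shift_matrix <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# translation offset of img relative to ref by phase correlation with
# parabolic sub-pixel peak interpolation
register_translation <- function(ref, img) {
  f1 <- stats::fft(ref); f2 <- stats::fft(img)
  cps <- f1 * Conj(f2)
  denom <- pmax(Mod(cps), 1e-12)
  cc <- Re(stats::fft(cps / denom, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(cc)
  subpix <- function(mat, p, axis) {
    i <- p[axis]
    im <- ((i - 2) %% n[axis]) + 1; ip <- (i %% n[axis]) + 1
    if (axis == 1) { y0 <- mat[im, p[2]]; y1 <- mat[i, p[2]]; y2 <- mat[ip, p[2]] }
    else { y0 <- mat[p[1], im]; y1 <- mat[p[1], i]; y2 <- mat[p[1], ip] }
    den <- y0 - 2 * y1 + y2
    if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  }
  off <- c(pk[1] - 1 + subpix(cc, pk, 1), pk[2] - 1 + subpix(cc, pk, 2))
  off <- ifelse(off > n / 2, off - n, off)
  unname(off)   # shift to apply to img so it aligns with ref
}

# bilinear sub-pixel shift of a matrix
shift_bilinear <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  yi <- seq_len(ny) - dy; xi <- seq_len(nx) - dx
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  get <- function(r, c) {
    r <- pmin(pmax(r, 1), ny); c <- pmin(pmax(c, 1), nx)
    m[cbind(rep(r, times = nx), rep(c, each = ny))]
  }
  a <- matrix(get(y0, x0), ny, nx); b <- matrix(get(y0, x0 + 1), ny, nx)
  cc <- matrix(get(y0 + 1, x0), ny, nx); d <- matrix(get(y0 + 1, x0 + 1), ny, nx)
  FY <- matrix(fy, ny, nx); FX <- matrix(fx, ny, nx, byrow = TRUE)
  a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX + cc * FY * (1 - FX) +
    d * FY * FX
}

#' Gaussian-weighted registered z-composite of a dendrite stack
#'
#' Each plane is registered (translation, phase correlation) to the
#' center plane, then planes are averaged with Gaussian weights over
#' plane index (weights normalized to sum 1).
#'
#' @param z_stack 3-D array (Z, Y, X) or a list of matrices.
#' @param center_plane index of the reference plane (default middle).
#' @param sigma_planes Gaussian sd of the plane weights.
#' @return composite image matrix.
#' @export
composite_projection <- function(z_stack, center_plane = NULL,
                                 sigma_planes = 1.5) {
  if (is.list(z_stack))
    z_stack <- simplify2array(z_stack)   # Y,X,Z
  if (length(dim(z_stack)) == 2) return(z_stack)
  if (dim(z_stack)[1] < dim(z_stack)[3]) {
    # assume (Z, Y, X); reorder to (Y, X, Z)
    z_stack <- aperm(z_stack, c(2, 3, 1))
  }
  nz <- dim(z_stack)[3]
  if (nz == 0) stop("empty stack")
  center_plane <- center_plane %||% ((nz + 1) %/% 2)
  ref <- z_stack[, , center_plane]
  w <- exp(-((seq_len(nz) - center_plane)^2) / (2 * sigma_planes^2))
  w <- w / sum(w)
  acc <- matrix(0, nrow(ref), ncol(ref))
  for (k in seq_len(nz)) {
    pl <- z_stack[, , k]
    if (k != center_plane && sd(pl) > 0 && sd(ref) > 0) {
      off <- register_translation(ref, pl)
      pl <- shift_bilinear(pl, off[1], off[2])
    }
    acc <- acc + w[k] * pl
  }
  acc
}

#' High-pass enhancement and Otsu binarization
#'
#' Background is removed by subtracting a large-kernel Gaussian
#' smoothing (high-pass, extracting low-amplitude spine features),
#' negatives clamped, and the result thresholded with Otsu's global
#' method. Optional rescue thresholds (fractions of the Otsu
#' threshold) union in components that the global threshold missed,
#' within optional rescue ROIs. Holes are filled and objects smaller
#' than `min_object_um2` removed.
#'
#' @param composite_image 2-D image.
#' @param rescue_thresholds numeric vector of fractions of the Otsu
#'   threshold (e.g. `c(0.5, 0.25)`); replaces manual re-thresholding.
#' @param rescue_rois optional list of logical masks limiting each
#'   rescue pass; `NULL` applies the pass everywhere.
#' @param highpass_sigma_px sd of the background smoothing kernel.
#' @param um_per_px image scale.
#' @param min_object_um2 minimal connected-object area kept.
#' @return logical binary mask.
#' @export
enhance_and_binarize <- function(composite_image, rescue_thresholds = NULL,
                                 rescue_rois = NULL,
                                 highpass_sigma_px = 20,
                                 um_per_px = 52 / 760,
                                 min_object_um2 = 1) {
  img <- composite_image
  if (sd(img) == 0) {
    warning("constant image; empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  # brush must fit inside the image
  sigma <- min(highpass_sigma_px, (min(dim(img)) - 1) / 7)
  bg <- EBImage::gblur(img, sigma = sigma)
  hp <- pmax(img - bg, 0)
  rng <- range(hp)
  hp01 <- (hp - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(hp01), range = c(0, 1))
  mask <- hp01 > thr
  if (!is.null(rescue_thresholds)) {
    for (i in seq_along(rescue_thresholds)) {
      low <- hp01 > thr * rescue_thresholds[i]
      roi <- if (!is.null(rescue_rois) && length(rescue_rois) >= i)
        rescue_rois[[i]] else matrix(TRUE, nrow(img), ncol(img))
      lab <- EBImage::bwlabel(low)
      keep_ids <- unique(lab[low & roi])
      keep_ids <- keep_ids[keep_ids > 0]
      mask <- mask | (lab %in% keep_ids & low)
    }
  }
  mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  min_px <- min_object_um2 / um_per_px^2
  small <- which(sizes < min_px)
  if (length(small)) mask[lab %in% small] <- FALSE
  matrix(as.logical(mask), nrow(img), ncol(img))
}

# Zhang-Suen thinning to a 1-px skeleton (vectorized over the image)
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  sh <- function(M, dy, dx) shift_matrix(M, dy, dx)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- sh(m, -1, 0); p3 <- sh(m, -1, 1); p4 <- sh(m, 0, 1)
      p5 <- sh(m, 1, 1); p6 <- sh(m, 1, 0); p7 <- sh(m, 1, -1)
      p8 <- sh(m, 0, -1); p9 <- sh(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# order skeleton pixels along the path from one endpoint; returns a
# matrix of (row, col) and cumulative arc length in px
order_skeleton <- function(skeleton) {
  pix <- which(skeleton, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0) stop("empty skeleton")
  if (n == 1) return(list(path = pix, arc = 0))
  key <- paste(pix[, 1], pix[, 2])
  idx <- seq_len(n); names(idx) <- key
  nbrs <- function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    cand <- expand.grid(r = r + (-1:1), c = c + (-1:1))
    k <- paste(cand$r, cand$c)
    out <- idx[k[k %in% key & k != paste(r, c)]]
    out[!is.na(out)]
  }
  deg <- vapply(idx, function(i) length(nbrs(i)), numeric(1))
  start <- if (any(deg == 1)) which(deg == 1)[1] else which.min(pix[, 2])
  visited <- logical(n); path <- integer(0); cur <- start
  while (!is.na(cur)) {
    visited[cur] <- TRUE; path <- c(path, cur)
    nb <- nbrs(cur); nb <- nb[!visited[nb]]
    cur <- if (length(nb)) nb[1] else NA_integer_
  }
  p <- pix[path, , drop = FALSE]
  steps <- if (nrow(p) > 1) sqrt(rowSums(diff(p)^2)) else numeric(0)
  list(path = p, arc = c(0, cumsum(steps)))
}

# Cauchy mean-breadth perimeter: for (near-)convex pixel sets the
# perimeter equals pi times the mean projection breadth over
# directions; robust for small discrete shapes where edge counting
# fails
perimeter_breadth <- function(coords) {
  if (nrow(coords) == 1) return(pi)
  th <- seq(0, pi - pi / 36, by = pi / 36)
  b <- vapply(th, function(a) {
    pr <- coords[, 1] * cos(a) + coords[, 2] * sin(a)
    diff(range(pr)) + 1
  }, numeric(1))
  pi * mean(b)
}

# ---- spine extraction and classification ----------------------------

#' Extract candidate spines from a binarized dendrite
#'
#' The shaft corridor (skeleton dilated to the shaft's median width
#' plus one pixel) is subtracted from the mask; remaining connected
#' components touching the corridor are candidate spines. For each
#' spine: the base is the pixel set adjacent to the corridor, length
#' is the Euclidean distance from the base midpoint to the most
#' distant pixel, the base-to-tip axis is divided into three equal
#' segments (base / neck / head), and neck length, head area, head
#' circularity (4*pi*A/P^2) and aspect ratio (length over maximal
#' width perpendicular to the axis) are computed from them.
#'
#' @param binary_mask logical dendrite mask.
#' @param skeleton logical 1-px shaft skeleton (inside the mask).
#' @param um_per_px image scale (um per pixel).
#' @param min_area_um2 minimal spine area included (paper default 1).
#' @param neck_mode `"width"` (extent where width < half the head
#'   width; default) or `"thirds"` (neck = length/3, the literal
#'   three-segment reading).
#' @return data frame of unclassified spine records: `id`,
#'   `base_x_px`, `base_y_px`, `arc_pos_um`, `length_um`,
#'   `neck_length_um`, `head_circularity`, `aspect_ratio`, `area_um2`,
#'   `head_width_um`.
#' @export
extract_spines <- function(binary_mask, skeleton, um_per_px = 52 / 760,
                           min_area_um2 = 1, neck_mode = c("width", "thirds")) {
  neck_mode <- match.arg(neck_mode)
  if (!any(skeleton)) stop("skeleton missing")
  skel_len <- sum(skeleton)
  shaft_area <- NULL
  # median shaft width from mask area near skeleton
  corr_r <- 1
  repeat {
    corridor <- EBImage::dilate(EBImage::Image(skeleton * 1),
                                EBImage::makeBrush(2 * corr_r + 1, "disc")) > 0.5
    cover <- sum(binary_mask & corridor) / max(sum(corridor), 1)
    if (cover < 0.75 || corr_r > 20) break
    corr_r <- corr_r + 1
  }
  corridor <- EBImage::dilate(EBImage::Image(skeleton * 1),
                              EBImage::makeBrush(2 * corr_r + 1, "disc")) > 0.5
  corridor <- matrix(as.logical(corridor), nrow(binary_mask), ncol(binary_mask))
  cand <- binary_mask & !corridor
  lab <- EBImage::bwlabel(cand)
  nl <- max(lab)
  if (nl == 0) return(empty_spine_table())
  ord <- order_skeleton(skeleton)
  # adjacency to corridor: dilate corridor by 1
  corr_d <- EBImage::dilate(EBImage::Image(corridor * 1),
                            EBImage::makeBrush(3, "box")) > 0.5
  recs <- list()
  id <- 0
  for (l in seq_len(nl)) {
    coords <- which(lab == l, arr.ind = TRUE)   # (row, col) = (y, x)
    area <- nrow(coords) * um_per_px^2
    if (area <= min_area_um2) next
    base_sel <- corr_d[coords]
    if (!any(base_sel)) next                    # not attached to shaft
    base <- coords[base_sel, , drop = FALSE]
    bmid <- colMeans(base)
    d <- sqrt((coords[, 1] - bmid[1])^2 + (coords[, 2] - bmid[2])^2)
    tip <- coords[which.max(d), ]
    len_px <- max(d)
    if (len_px < 1) next
    u <- (tip - bmid) / len_px
    t_px <- (coords[, 1] - bmid[1]) * u[1] + (coords[, 2] - bmid[2]) * u[2]
    w_px <- -(coords[, 1] - bmid[1]) * u[2] + (coords[, 2] - bmid[2]) * u[1]
    # width profile in 1-px axial bins
    tb <- pmin(pmax(floor(t_px), 0), ceiling(len_px) - 1)
    prof <- tapply(w_px, tb, function(w) diff(range(w)) + 1)
    prof_t <- as.numeric(names(prof)) + 0.5
    head_lo <- 2 * len_px / 3
    head_sel <- t_px >= head_lo
    head_coords <- coords[head_sel, , drop = FALSE]
    head_width_px <- if (any(prof_t >= head_lo))
      max(prof[prof_t >= head_lo]) else max(prof)
    max_width_px <- max(prof)
    if (neck_mode == "width") {
      below <- prof_t < head_lo & prof < 0.5 * head_width_px
      neck_px <- sum(below)
    } else {
      neck_px <- len_px / 3
    }
    head_area_px <- nrow(head_coords)
    circ <- if (head_area_px >= 2) {
      P <- perimeter_breadth(head_coords)
      min(4 * pi * head_area_px / P^2, 1)
    } else 1
    # arc position of the base along the skeleton
    dk <- sqrt((ord$path[, 1] - bmid[1])^2 + (ord$path[, 2] - bmid[2])^2)
    arc_um <- ord$arc[which.min(dk)] * um_per_px
    id <- id + 1
    recs[[id]] <- data.frame(
      id = id, base_y_px = bmid[1], base_x_px = bmid[2],
      arc_pos_um = arc_um, length_um = len_px * um_per_px,
      neck_length_um = neck_px * um_per_px,
      head_circularity = circ,
      aspect_ratio = len_px / max_width_px,
      area_um2 = area, head_width_um = head_width_px * um_per_px)
  }
  if (length(recs) == 0) return(empty_spine_table())
  do.call(rbind, recs)
}

empty_spine_table <- function() {
  data.frame(id = integer(0), base_y_px = numeric(0), base_x_px = numeric(0),
             arc_pos_um = numeric(0), length_um = numeric(0),
             neck_length_um = numeric(0), head_circularity = numeric(0),
             aspect_ratio = numeric(0), area_um2 = numeric(0),
             head_width_um = numeric(0))
}

#' Default spine classification thresholds
#'
#' Verbatim published values: stubby (neck < 0.2 um and aspect < 1.3),
#' mushroom (neck > 0.2 um, head circularity > 0.8), filopodium
#' (neck > 0.2 um, length < 0.8 um, aspect > 1.3), thin (neck >
#' 0.2 um, length < 0.7 um, circularity < 0.8). The published
#' categories overlap; precedence stubby -> mushroom -> filopodium ->
#' thin resolves ties, with thin as the fallback.
#'
#' @return named list of thresholds.
#' @export
spine_class_thresholds <- function() {
  list(neck_um = 0.2, stubby_aspect = 1.3, mushroom_circ = 0.8,
       filo_length_um = 0.8, filo_aspect = 1.3, thin_length_um = 0.7,
       thin_circ = 0.8)
}

#' Classify one spine record into a morphological class
#'
#' @param record one row from [extract_spines()] (or any list with
#'   `neck_length_um`, `length_um`, `head_circularity`,
#'   `aspect_ratio`).
#' @param thresholds see [spine_class_thresholds()].
#' @return one of `"stubby"`, `"mushroom"`, `"filopodium"`, `"thin"`,
#'   with attribute `fallback = TRUE` when no published rule matched.
#' @export
classify_spine <- function(record, thresholds = spine_class_thresholds()) {
  th <- thresholds
  neck <- record$neck_length_um; len <- record$length_um
  circ <- record$head_circularity; asp <- record$aspect_ratio
  if (neck < th$neck_um && asp < th$stubby_aspect) return("stubby")
  if (neck > th$neck_um && circ > th$mushroom_circ) return("mushroom")
  if (neck > th$neck_um && len < th$filo_length_um && asp > th$filo_aspect)
    return("filopodium")
  if (neck > th$neck_um && len < th$thin_length_um && circ < th$thin_circ)
    return("thin")
  structure("thin", fallback = TRUE)
}

#' Analyze a composite dendrite image into a session record
#'
#' Binarizes, skeletonizes the shaft (morphological opening removes
#' the thin spines before thinning), extracts and classifies spines.
#'
#' @param composite_image 2-D image (or an already-binary mask).
#' @param um_per_px image scale.
#' @param min_area_um2 spine inclusion area.
#' @param opening_radius_px radius of the shaft-isolating opening.
#' @param ... passed to [enhance_and_binarize()].
#' @return list of class `dendrite_session`: `binary_mask`,
#'   `skeleton`, `dendrite_length_um`, `spines` (classified records).
#' @export
analyze_dendrite <- function(composite_image, um_per_px = 52 / 760,
                             min_area_um2 = 1, opening_radius_px = 5,
                             ...) {
  if (is.logical(composite_image)) mask <- composite_image
  else mask <- enhance_and_binarize(composite_image,
                                    um_per_px = um_per_px, ...)
  shaft <- EBImage::opening(EBImage::Image(mask * 1),
                            EBImage::makeBrush(2 * opening_radius_px + 1,
                                               "disc")) > 0.5
  shaft <- matrix(as.logical(shaft), nrow(mask), ncol(mask))
  skel <- skeletonize_mask(shaft)
  spines <- extract_spines(mask, skel, um_per_px = um_per_px,
                           min_area_um2 = min_area_um2)
  if (nrow(spines) > 0)
    spines$class <- vapply(seq_len(nrow(spines)), function(i)
      classify_spine(spines[i, ]), character(1))
  else spines$class <- character(0)
  structure(list(binary_mask = mask, skeleton = skel,
                 dendrite_length_um = sum(skel) * um_per_px,
                 um_per_px = um_per_px, spines = spines),
            class = "dendrite_session")
}

#' Spine density per 10 um of dendrite
#'
#' `S_section = S_total / (D_length_px * um_per_px) * 10`, with the
#' dendrite length taken as the skeleton pixel count times the pixel
#' size; also per morphological class.
#'
#' @param session a `dendrite_session` from [analyze_dendrite()].
#' @return list `total_per_10um`, `per_class_per_10um`.
#' @export
spine_density <- function(session) {
  len_um <- session$dendrite_length_um
  if (len_um <= 0) stop("zero-length skeleton")
  classes <- c("stubby", "mushroom", "filopodium", "thin")
  per_class <- vapply(classes, function(cl)
    sum(session$spines$class == cl) / len_um * 10, numeric(1))
  list(total_per_10um = nrow(session$spines) / len_um * 10,
       per_class_per_10um = per_class)
}

#' Match spines between two sessions by arc position
#'
#' Greedy nearest matching of spines along the shaft arc within
#' `max_offset_um`; unmatched spines in the later session are added,
#' unmatched in the earlier are subtracted. When skeletons are
#' supplied, registration is verified by requiring >= 50% shaft
#' overlap.
#'
#' @param spines_a,spines_b spine record tables (must have
#'   `arc_pos_um`, `id`, optionally `class`).
#' @param max_offset_um matching tolerance along the arc.
#' @param skeleton_a,skeleton_b optional logical skeletons for the
#'   registration check.
#' @param curation optional data frame with columns `id_a`, `id_b`
#'   overriding automated matches (NA in one column forces
#'   added/subtracted).
#' @return list `matches` (data frame `id_a`, `id_b`), `added_ids`
#'   (ids in b), `subtracted_ids` (ids in a).
#' @export
match_spines_across_days <- function(spines_a, spines_b,
                                     max_offset_um = 1.0,
                                     skeleton_a = NULL, skeleton_b = NULL,
                                     curation = NULL) {
  if (!is.null(skeleton_a) && !is.null(skeleton_b)) {
    corr <- EBImage::dilate(EBImage::Image(skeleton_b * 1),
                            EBImage::makeBrush(5, "disc")) > 0.5
    overlap <- sum(skeleton_a & corr) / max(sum(skeleton_a), 1)
    if (overlap < 0.5)
      stop("sessions appear unregistered (shaft overlap < 50%)")
  }
  forced <- if (!is.null(curation)) curation else
    data.frame(id_a = integer(0), id_b = integer(0))
  free_a <- setdiff(spines_a$id, forced$id_a)
  free_b <- setdiff(spines_b$id, forced$id_b)
  pairs <- expand.grid(ia = seq_along(free_a), ib = seq_along(free_b))
  matches <- forced[!is.na(forced$id_a) & !is.na(forced$id_b), , drop = FALSE]
  if (nrow(pairs) > 0) {
    pa <- spines_a$arc_pos_um[match(free_a, spines_a$id)]
    pb <- spines_b$arc_pos_um[match(free_b, spines_b$id)]
    pairs$d <- abs(pa[pairs$ia] - pb[pairs$ib])
    pairs <- pairs[pairs$d <= max_offset_um, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used_a <- logical(length(free_a)); used_b <- logical(length(free_b))
    for (r in seq_len(nrow(pairs))) {
      ia <- pairs$ia[r]; ib <- pairs$ib[r]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      matches <- rbind(matches,
                       data.frame(id_a = free_a[ia], id_b = free_b[ib]))
    }
  }
  list(matches = matches,
       added_ids = setdiff(spines_b$id, matches$id_b),
       subtracted_ids = setdiff(spines_a$id, matches$id_a))
}

#' Build a turnover ledger from a series of sessions
#'
#' Chains pairwise matches across consecutive days, assigning global
#' spine identities. A spine lost and later re-found at the same
#' position counts as a new spine (re-appearances disallowed).
#'
#' @param spine_tables list of per-day spine record tables (with
#'   `id`, `arc_pos_um`, `class`).
#' @param max_offset_um matching tolerance.
#' @return list of class `turnover_ledger`: `n_days`, `counts` (spines
#'   per day), `pairs` (per day-pair: `added`, `subtracted`,
#'   `added_by_class`, `subtracted_by_class`, `n_mean`),
#'   `original_present` (logical matrix originals x days).
#' @export
build_turnover_ledger <- function(spine_tables, max_offset_um = 1.0) {
  nd <- length(spine_tables)
  stopifnot(nd >= 1)
  classes <- c("stubby", "mushroom", "filopodium", "thin")
  gids <- list()
  gids[[1]] <- seq_len(nrow(spine_tables[[1]]))
  next_gid <- length(gids[[1]]) + 1
  pairs <- list()
  for (d in seq_len(nd - 1)) {
    a <- spine_tables[[d]]; b <- spine_tables[[d + 1]]
    m <- match_spines_across_days(a, b, max_offset_um)
    gb <- rep(NA_integer_, nrow(b))
    if (nrow(m$matches) > 0) {
      gb[match(m$matches$id_b, b$id)] <-
        gids[[d]][match(m$matches$id_a, a$id)]
    }
    new <- which(is.na(gb))
    if (length(new)) {
      gb[new] <- seq(next_gid, length.out = length(new))
      next_gid <- next_gid + length(new)
    }
    gids[[d + 1]] <- gb
    cls_b <- if ("class" %in% names(b)) b$class else rep(NA, nrow(b))
    cls_a <- if ("class" %in% names(a)) a$class else rep(NA, nrow(a))
    add_cls <- table(factor(cls_b[b$id %in% m$added_ids], levels = classes))
    sub_cls <- table(factor(cls_a[a$id %in% m$subtracted_ids],
                            levels = classes))
    pairs[[d]] <- list(added = length(m$added_ids),
                       subtracted = length(m$subtracted_ids),
                       added_by_class = as.numeric(add_cls),
                       subtracted_by_class = as.numeric(sub_cls),
                       n_mean = (nrow(a) + nrow(b)) / 2)
  }
  originals <- gids[[1]]
  present <- vapply(seq_len(nd), function(d) originals %in% gids[[d]],
                    logical(length(originals)))
  if (length(originals) == 1) present <- matrix(present, nrow = 1)
  structure(list(n_days = nd,
                 counts = vapply(spine_tables, nrow, numeric(1)),
                 pairs = pairs, classes = classes,
                 original_present = present),
            class = "turnover_ledger")
}

#' Turnover percentages per day pair
#'
#' `S_a/s = N_a/s(t) / N(t) * 100` with `N(t)` the mean total spine
#' count of the pair; per-class turnover is normalized to the total
#' cumulative turnover (added + subtracted) of that day pair.
#'
#' @param ledger a [build_turnover_ledger()] result.
#' @return data frame per day pair: `pct_added`, `pct_subtracted`,
#'   plus normalized per-class turnover shares
#'   (`share_stubby`, ... summing to 1 when any turnover occurred).
#' @export
turnover_stats <- function(ledger) {
  stopifnot(length(ledger$pairs) >= 1)
  out <- lapply(seq_along(ledger$pairs), function(d) {
    p <- ledger$pairs[[d]]
    tot_turn <- p$added + p$subtracted
    shares <- if (tot_turn > 0)
      (p$added_by_class + p$subtracted_by_class) / tot_turn
    else rep(0, length(ledger$classes))
    stats <- data.frame(
      pair = d,
      pct_added = if (p$n_mean > 0) p$added / p$n_mean * 100 else 0,
      pct_subtracted = if (p$n_mean > 0) p$subtracted / p$n_mean * 100 else 0)
    for (i in seq_along(ledger$classes))
      stats[[paste0("share_", ledger$classes[i])]] <- shares[i]
    stats
  })
  do.call(rbind, out)
}

#' Survival fraction curve S(t)
#'
#' `S(t_n) = N_r(t_n) / N(t_0) * 100`: the percentage of day-1 spines
#' still present (by chained identity) on day n. `S(0) = 100`.
#'
#' @param ledger a [build_turnover_ledger()] result.
#' @return data frame `day` (1-based), `survival_pct`.
#' @export
survival_fraction <- function(ledger) {
  n0 <- nrow(ledger$original_present)
  if (n0 == 0) stop("no day-1 spines")
  data.frame(day = seq_len(ledger$n_days),
             survival_pct = colSums(ledger$original_present) / n0 * 100)
}
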