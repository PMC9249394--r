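# Synthetic dendrite images with spines of the four morphological
# classes at known geometry, and multi-day series with known turnover.

# half-width profile (um) along the spine axis for each class; the
# geometries are chosen to satisfy their own class under the published
# thresholds after pixelization and shaft-corridor subtraction
spine_profile <- function(class) {
  switch(class,
    stubby = list(length_um = 0.50, hw = function(t) rep(0.25, length(t))),
    mushroom = list(length_um = 1.96, hw = function(t) {
      ifelse(t < 1.30, 0.10,
             pmax(sqrt(pmax(0.33^2 - (t - 1.63)^2, 0)), 0.02))
    }),
    thin = list(length_um = 0.54, hw = function(t) {
      ifelse(t < 0.30, 0.10,
             pmax(0.28 * sqrt(pmax(1 - ((t - 0.42) / 0.13)^2, 0)), 0.02))
    }),
    filopodium = list(length_um = 0.72, hw = function(t) {
      ifelse(t < 0.48, 0.069, 0.17)
    }),
    stop("unknown spine class: ", class))
}

#' Specification for a synthetic dendrite image
#'
#' A straight horizontal shaft with spines of the four morphological
#' classes projecting laterally, rendered at the acquisition scale of
#' 52 um across 760 px (0.0684 um/px). Spine geometries are fixed
#' per class and satisfy their own class under the published
#' classification thresholds.
#'
#' @param image_shape_px (rows, cols).
#' @param um_per_px image scale.
#' @param n_spines_per_class counts for stubby, mushroom, filopodium,
#'   thin (in that order).
#' @param shaft_width_um shaft diameter (um).
#' @param spacing_um minimal spacing between spine bases along the
#'   shaft.
#' @param intensity foreground intensity; background is 0.
#' @param background_sd Gaussian noise sd (0 = noiseless).
#' @param seed integer seed.
#' @return a `sim_dendrite_spec` list.
#' @export
sim_dendrite_spec <- function(image_shape_px = c(220, 520),
                              um_per_px = 52 / 760,
                              n_spines_per_class = c(3, 3, 3, 3),
                              shaft_width_um = 0.8, spacing_um = 2.2,
                              intensity = 1, background_sd = 0,
                              seed = 1) {
  stopifnot(um_per_px > 0, length(n_spines_per_class) == 4)
  structure(as.list(environment()), class = "sim_dendrite_spec")
}

# render one spine into a logical mask; returns modified mask
draw_spine <- function(mask, x_px, shaft_edge_y, dir, class, um_per_px,
                       root_um = 0.15) {
  g <- spine_profile(class)
  n_t <- ceiling((g$length_um + root_um) / um_per_px)
  for (k in seq_len(n_t)) {
    t_um <- (k - 0.5) * um_per_px - root_um
    hw_um <- g$hw(max(t_um, 0))
    w_px <- max(1, round(2 * hw_um / um_per_px))
    x_lo <- x_px - floor((w_px - 1) / 2)
    cols <- x_lo:(x_lo + w_px - 1)
    y <- shaft_edge_y + dir * (k - 1)
    cols <- cols[cols >= 1 & cols <= ncol(mask)]
    if (y >= 1 && y <= nrow(mask)) mask[y, cols] <- TRUE
  }
  mask
}

# render a dendrite mask from a table of spines
render_dendrite <- function(spec, spines) {
  dims <- spec$image_shape_px
  mask <- matrix(FALSE, dims[1], dims[2])
  cy <- round(dims[1] / 2)
  hw <- max(1, round(spec$shaft_width_um / spec$um_per_px / 2))
  x0 <- 10; x1 <- dims[2] - 10
  mask[(cy - hw):(cy + hw), x0:x1] <- TRUE
  if (nrow(spines) > 0) for (i in seq_len(nrow(spines))) {
    edge_y <- if (spines$dir[i] > 0) cy + hw + 1 else cy - hw - 1
    mask <- draw_spine(mask, spines$x_px[i], edge_y, spines$dir[i],
                       spines$class[i], spec$um_per_px)
  }
  mask
}

# truth record for the spine layout of one day
new_spine_layout <- function(spec) {
  classes <- rep(c("stubby", "mushroom", "filopodium", "thin"),
                 times = spec$n_spines_per_class)
  n <- length(classes)
  dims <- spec$image_shape_px
  x0 <- 10 + 20; x1 <- dims[2] - 10 - 20
  spacing_px <- spec$spacing_um / spec$um_per_px
  xs <- seq(x0, x1, length.out = max(n, 2))[seq_len(n)]
  if (n > 1 && diff(xs[1:2]) < spacing_px)
    stop("image too small for requested spine count at given spacing")
  data.frame(id = seq_len(n), class = sample(classes),
             x_px = round(xs), dir = rep(c(1, -1), length.out = n))
}

#' Simulate a synthetic dendrite image
#'
#' @param spec a [sim_dendrite_spec()].
#' @return list with `image` (numeric matrix), `mask` (logical truth),
#'   `truth` (spine table: `id`, `class`, `x_px`, `dir`,
#'   `arc_pos_um`).
#' @export
simulate_dendrite <- function(spec) {
  stopifnot(inherits(spec, "sim_dendrite_spec"))
  set.seed(spec$seed)
  spines <- new_spine_layout(spec)
  mask <- render_dendrite(spec, spines)
  img <- mask * spec$intensity
  if (spec$background_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, spec$background_sd),
                        nrow(img), ncol(img))
  spines$arc_pos_um <- (spines$x_px - 10) * spec$um_per_px
  list(image = img, mask = mask, truth = spines)
}

#' Simulate a multi-day dendrite series with known turnover
#'
#' Day 1 realizes all specified spines; on each subsequent day every
#' existing spine is removed with probability `daily_sub_frac` and
#' `round(daily_add_frac * N)` new spines (random classes, free
#' positions) appear. All days share the shaft. The true ledger
#' records every event.
#'
#' @param spec a [sim_dendrite_spec()].
#' @param days number of sessions.
#' @param daily_add_frac,daily_sub_frac per-day event fractions in
#'   `[0, 1)`.
#' @return list with `images` (list of matrices), `masks`, `truth`
#'   (list of per-day spine tables with stable `id`), `events`
#'   (per day-pair true added/subtracted ids).
#' @export
simulate_dendrite_timeseries <- function(spec, days = 5,
                                         daily_add_frac = 0.05,
                                         daily_sub_frac = 0.05) {
  stopifnot(daily_add_frac >= 0, daily_add_frac < 1,
            daily_sub_frac >= 0, daily_sub_frac < 1)
  set.seed(spec$seed)
  layout <- new_spine_layout(spec)
  dims <- spec$image_shape_px
  spacing_px <- spec$spacing_um / spec$um_per_px
  all_x <- seq(10 + 20, dims[2] - 10 - 20, by = ceiling(spacing_px))
  next_id <- max(layout$id) + 1
  truth <- list(layout)
  events <- list()
  cur <- layout
  for (d in seq_len(days - 1)) {
    drop <- runif(nrow(cur)) < daily_sub_frac
    subtracted <- cur$id[drop]
    nxt <- cur[!drop, , drop = FALSE]
    n_add <- round(daily_add_frac * nrow(cur))
    added <- integer(0)
    if (n_add > 0) {
      # keep additions away from spines of either day so that added
      # and subtracted events stay identifiable by position
      occupied <- c(nxt$x_px, cur$x_px)
      free <- all_x[!vapply(all_x, function(x)
        any(abs(x - occupied) < spacing_px), logical(1))]
      n_add <- min(n_add, length(free))
      if (n_add > 0) {
        newx <- sample(free, n_add)
        news <- data.frame(
          id = seq(next_id, length.out = n_add),
          class = sample(c("stubby", "mushroom", "filopodium", "thin"),
                         n_add, replace = TRUE),
          x_px = newx, dir = sample(c(1, -1), n_add, replace = TRUE))
        next_id <- next_id + n_add
        added <- news$id
        nxt <- rbind(nxt, news)
      }
    }
    events[[d]] <- list(added = added, subtracted = subtracted)
    truth[[d + 1]] <- nxt
    cur <- nxt
  }
  masks <- lapply(truth, function(tb) render_dendrite(spec, tb))
  images <- lapply(masks, function(m) {
    img <- m * spec$intensity
    if (spec$background_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$background_sd),
                          nrow(img), ncol(img))
    img
  })
  truth <- lapply(truth, function(tb) {
    tb$arc_pos_um <- (tb$x_px - 10) * spec$um_per_px
    tb
  })
  list(images = images, masks = masks, truth = truth, events = events)
}
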