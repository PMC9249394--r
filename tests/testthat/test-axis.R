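test_that("rotation search recovers a noiseless rotated parabola", {
  ax <- simulate_axis_cells(a = 0.002, b = 250, c = 100, rotation_deg = 30,
                            n_cells = 150, jitter_px = 0, seed = 3)
  g <- fit_axis_curve(ax$centroids_px)
  expect_lte(min(abs(g$rotation_deg - 30), 180 - abs(g$rotation_deg - 30)), 1)
  expect_lt(abs(g$parabola["b"] - 250), 1)
  expect_gt(g$fit_r2, 0.999)
  # axis-aligned parabola selects rotation 0 (mod 180)
  ax0 <- simulate_axis_cells(rotation_deg = 0, jitter_px = 0, seed = 4)
  g0 <- fit_axis_curve(ax0$centroids_px)
  expect_lte(min(g0$rotation_deg, 180 - g0$rotation_deg), 1)
  # equivariance: rotating all centroids shifts the recovered rotation
  rot <- hippo2p:::rotate_xy(ax0$centroids_px, -40)
  g40 <- fit_axis_curve(rot)
  expect_lte(min(abs(g40$rotation_deg - 40), 180 - abs(g40$rotation_deg - 40)),
             1)
  expect_error(fit_axis_curve(ax$centroids_px[1:10, ]), "20")
  expect_error(fit_axis_curve(cbind(1:50, 2 * (1:50))), "degenerate")
})

test_that("arc distances are signed, symmetric, and match dense sampling", {
  g <- structure(list(rotation_deg = 0,
                      parabola = c(a = 0.002, b = 250, c = 100),
                      inflection_xy_px = c(250, 100), fit_r2 = 1),
                 class = "axis_geometry")
  # vertex maps to zero
  expect_equal(cell_axis_distance(g, c(250, 100)), 0, tolerance = 1e-6)
  # point on the curve at known x: arc length by dense sampling oracle
  x1 <- 330
  y1 <- 0.002 * (x1 - 250)^2 + 100
  xs <- seq(250, x1, length.out = 20000)
  oracle <- sum(sqrt(1 + (2 * 0.002 * (xs - 250))^2)) * (x1 - 250) / 20000
  d <- cell_axis_distance(g, c(x1, y1), um_per_px = 1)
  expect_equal(abs(d), oracle, tolerance = 0.01 * oracle)
  # mirror symmetry
  d2 <- cell_axis_distance(g, c(250 - 80, 0.002 * 80^2 + 100))
  d3 <- cell_axis_distance(g, c(250 + 80, 0.002 * 80^2 + 100))
  expect_equal(abs(d2), abs(d3), tolerance = 1e-6)
  expect_equal(sign(d2), -sign(d3))
})

test_that("sliding-window profile flags injected steps, not flat nulls", {
  set.seed(21)
  d <- runif(400, -600, 600)
  # flat SI: few or no windows flagged
  si_flat <- rnorm(400, 0.5, 0.15)
  pr <- sliding_window_profile(d, si_flat, n_boot = 200, n_shuffle = 400,
                               seed = 1)
  expect_lte(mean(pr$flagged, na.rm = TRUE), 0.15)
  # injected +50% step below zero: left windows flagged high
  si_step <- rnorm(400, 0.5, 0.1) + 0.25 * (d < 0)
  pr2 <- sliding_window_profile(d, si_step, n_boot = 200, n_shuffle = 400,
                                seed = 1)
  left <- pr2$center_um < -100
  expect_gte(mean(pr2$flagged[left]), 0.8)
  # bootstrap s.e.m. close to the closed form sd/sqrt(n)
  prb <- sliding_window_profile(d, si_flat, n_boot = 1000, n_shuffle = 50,
                                seed = 2)
  w <- which.max(prb$n_cells)
  sel <- d >= prb$center_um[w] - 100 & d < prb$center_um[w] + 100
  closed <- sd(si_flat[sel]) / sqrt(sum(sel))
  expect_lt(abs(prb$boot_sem[w] - closed) / closed, 0.10)
  expect_error(sliding_window_profile(d[1:30], si_flat[1:30]), "50")
})

test_that("flat-model F-test matches ANOVA and calibrates its size", {
  # hand-computable 3-bin dataset
  d <- c(-500, -450, -100, -50, 0, 350, 400, 450, -300, 250, 150, -250)
  si <- c(1, 2, 2, 3, 4, 5, 6, 7, 1.5, 5.5, 4.5, 2.5)
  ft <- flat_f_test(d, si, n_bins = 3)
  bins <- cut(d, seq(-600, 600, length.out = 4), include.lowest = TRUE)
  ref <- anova(lm(si ~ bins))
  expect_equal(ft$f_stat, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(ft$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(ft$df1, 2); expect_equal(ft$df2, 9)
  # all equal -> F = 0, p = 1
  f0 <- flat_f_test(rep(c(-300, 300), 10), rep(2, 20), n_bins = 2)
  expect_equal(f0$f_stat, 0)
  expect_equal(f0$p, 1)
  # zero residual -> infinite F, p -> 0
  fi <- flat_f_test(c(-300, -300, 300, 300), c(1, 1, 3, 3), n_bins = 2)
  expect_true(is.infinite(fi$f_stat))
  expect_equal(fi$p, 0)
  expect_error(flat_f_test(rep(-300, 10), rnorm(10), n_bins = 5), "empty")
  # type-I error near the nominal 5% under a flat null
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    dd <- runif(150, -600, 600)
    flat_f_test(dd, rnorm(150, 1, 0.3))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  # power at a 50% gradient effect
  pow <- vapply(1:100, function(s) {
    set.seed(s + 5000)
    dd <- runif(150, -600, 600)
    ss <- rnorm(150, 0.5, 0.15) + 0.25 * (dd / 600)
    flat_f_test(dd, ss)$p < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.8)
})
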