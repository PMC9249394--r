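test_that("track geometry matches the published dimensions", {
  tr <- make_track(250, 140, 72)
  expect_equal(tr$midline_circumference_cm, pi * 195 / 10)
  expect_equal(round(tr$midline_circumference_cm, 2), 61.26)
  expect_equal(round(tr$bin_length_cm, 2), 0.85)
  expect_equal(length(tr$bin_edges_cm), 73)
  expect_equal(tr$bin_edges_cm[1], 0)
  expect_equal(tr$bin_edges_cm[73], tr$midline_circumference_cm)
  # degenerate zero-width annulus reduces to a circle of radius r
  tr2 <- make_track(200, 199.999, 10)
  expect_equal(tr2$midline_circumference_cm, pi * 199.9995 / 10,
               tolerance = 1e-6)
  expect_error(make_track(100, 150), "outer")
})

test_that("circular median handles wraparound and unwrapping accumulates", {
  expect_equal(circ_median(c(350, 10) * pi / 180), 0, tolerance = 1e-9)
  expect_equal(circ_median(c(10, 20, 100) * pi / 180), 20 * pi / 180,
               tolerance = 1e-9)
  th <- seq(0, 6 * pi, length.out = 1000)
  expect_equal(unwrap_angle(th %% (2 * pi)), th, tolerance = 1e-9)
})

test_that("frame aggregation agrees with a brute-force grouping oracle", {
  set.seed(7)
  n <- 2000
  samples <- data.frame(
    time_s = sort(runif(n, 0, 50)),
    angle_deg = runif(n, 0, 360),
    speed_mm_s = runif(n, 0, 200),
    heading_deg = runif(n, 0, 360),
    x_mm = rnorm(n), y_mm = rnorm(n))
  ft <- seq(0, 49.9, by = 0.1)
  fr <- aggregate_to_frames(samples, ft)
  # brute-force oracle over a sample of frames
  for (k in sample(seq_along(ft), 50)) {
    lo <- ft[k]; hi <- ft[k] + 0.1
    sel <- samples$time_s >= lo & samples$time_s < hi
    if (!any(sel)) next
    expect_equal(fr$speed_mm_s[k], median(samples$speed_mm_s[sel]))
    expect_equal(fr$angle_rad[k],
                 circ_median(samples$angle_deg[sel] * pi / 180),
                 tolerance = 1e-9)
  }
  # empty frames are flagged and carry the previous value forward
  sparse <- samples[samples$time_s < 10 | samples$time_s > 20, ]
  fr2 <- aggregate_to_frames(sparse, ft)
  gap <- ft >= 10.1 & ft < 20
  expect_true(all(fr2$imputed[gap]))
  expect_true(all(!is.na(fr2$speed_mm_s)))
})

test_that("movement mask applies duration and buffer rules", {
  rate <- 10
  # 0.8 s supra-threshold run: excluded entirely
  sp <- rep(0, 100); sp[41:48] <- 100
  expect_false(any(movement_mask(sp, rate, smooth = FALSE)))
  # 2.0 s run: 20 frames + 5 buffer frames each side (interior)
  sp <- rep(0, 100); sp[41:60] <- 100
  m <- movement_mask(sp, rate, smooth = FALSE)
  expect_equal(sum(m), 30)
  expect_true(all(m[36:65]))
  # zero speed: all false
  expect_false(any(movement_mask(rep(0, 100), rate)))
  # kept epochs are never shorter than min_dur + 2*buffer (interior)
  set.seed(3)
  sp <- pmax(0, 60 * sin(seq(0, 40, by = 0.1)) + rnorm(401, 0, 10))
  m <- movement_mask(sp, rate)
  runs <- rle(m)
  interior <- runs$lengths[runs$values]
  if (length(interior) > 2) interior <- interior[2:(length(interior) - 1)]
  expect_true(all(interior >= 1.0 * rate + 2 * 0.5 * rate))
})

test_that("lap segmentation matches an unwrap oracle and drops fast laps", {
  # monotone sweep of just over 3 full turns -> 3 laps
  ang <- seq(0, 6.02 * pi, length.out = 600) %% (2 * pi)
  laps <- segment_laps(ang)
  expect_equal(length(laps$lap_kept), 3)
  expect_true(all(laps$lap_id[laps$lap_id > 0] %in% 1:3))
  # constant 200 mm/s lap flagged not kept
  laps2 <- segment_laps(ang, rep(200, 600))
  expect_false(any(laps2$lap_kept))
  # direction reversals must be made up before a lap completes
  ang3 <- c(seq(0, pi, length.out = 100), seq(pi, 0.5 * pi, length.out = 50),
            seq(0.5 * pi, 2.1 * pi, length.out = 200)) %% (2 * pi)
  laps3 <- segment_laps(ang3)
  expect_equal(length(laps3$lap_kept), 1)
  # oracle equality on a synthetic session
  ses <- small_session()
  u <- unwrap_angle(ses$frames$angle_rad)
  n_expected <- floor(abs(u[length(u)] - u[1]) / (2 * pi))
  expect_equal(length(attr(ses$frames, "lap_kept")), n_expected)
  expect_warning(segment_laps(rep(0.1, 50)), "no completed laps")
})
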