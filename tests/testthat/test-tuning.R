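test_that("tuning curves equal a brute-force binning oracle", {
  ses <- small_session()
  fr <- ses$frames; tr <- ses$track
  lk <- attr(fr, "lap_kept")
  act <- ses$dff[1, ]
  tc <- spatial_tuning_curves(act, fr$position_cm, fr$moving, fr$lap_id,
                              tr, lk, dt_s = 0.1)
  # brute-force double loop over a few laps
  kept <- tc$kept_laps
  bins <- floor(fr$position_cm / tr$bin_length_cm) + 1
  for (li in sample(seq_along(kept), 3)) {
    l <- kept[li]
    for (k in sample(1:72, 10)) {
      sel <- fr$moving & fr$lap_id == l & bins == k
      expected <- if (!any(sel)) NA_real_ else sum(act[sel]) / (sum(sel) * 0.1)
      expect_equal(tc$per_lap_curves[li, k], expected, tolerance = 1e-9)
    }
  }
  # constant activity with uniform occupancy -> flat curve
  n <- 720 * 4
  pos <- rep(seq(0.05, 61.2, length.out = 720), 4)
  lap <- rep(1:4, each = 720)
  tc2 <- spatial_tuning_curves(rep(2, n), pos, rep(TRUE, n), lap, tr,
                               rep(TRUE, 4), dt_s = 0.1)
  expect_true(all(abs(tc2$mean_curve - 20) < 1e-9))
  # activity confined to one bin stays in that bin
  act3 <- as.numeric(bins == 10)
  tc3 <- spatial_tuning_curves(act3, fr$position_cm, fr$moving, fr$lap_id,
                               tr, lk, dt_s = 0.1)
  expect_true(all(tc3$mean_curve[-10] == 0 | is.na(tc3$mean_curve[-10])))
  expect_gt(tc3$mean_curve[10], 0)
})

test_that("circular permutation preserves each lap's curve mass", {
  set.seed(11)
  pc <- matrix(rexp(20 * 72), 20, 72)
  sh <- hippo2p:::shift_rows_circular(pc, sample.int(71, 20, replace = TRUE))
  expect_equal(rowSums(sh), rowSums(pc))
  expect_false(all(sh == pc))
})

test_that("consistency test separates reliable bumps from noise", {
  # identical sharp bumps -> consistent
  bump <- dnorm(1:72, 30, 3)
  pc <- matrix(rep(bump, 12), 12, 72, byrow = TRUE) +
    matrix(rnorm(12 * 72, 0, 1e-3), 12, 72)
  ct <- consistency_test(pc, seed = 1)
  expect_true(ct$consistent)
  expect_gt(mean(ct$real_split_corrs, na.rm = TRUE), 0.9)
  expect_gt(ct$cohens_d, 0.5)
  expect_lt(ct$ks_p, 0.01)
  # i.i.d. noise curves -> consistent in at most 5% of seeds
  fp <- vapply(1:20, function(s) {
    set.seed(s)
    consistency_test(matrix(rnorm(20 * 72), 20, 72), seed = s)$consistent
  }, logical(1))
  expect_lte(mean(fp), 0.05)
  expect_error(consistency_test(matrix(1, 4, 72)), "6 kept laps")
})

test_that("Gaussian field fit recovers parameters and applies criteria", {
  tr <- make_track()
  x <- (1:72 - 0.5) * tr$bin_length_cm
  # noiseless Gaussian, C = 12 -> FWHM 19.98, near-perfect fit
  curve <- 0.2 + 1.0 * exp(-((x - 30) / 12)^2)
  f <- fit_gaussian_field(curve, tr)
  expect_equal(f$fwhm_cm, 2 * 12 * sqrt(log(2)), tolerance = 0.01)
  expect_equal(f$fwhm_cm, 19.98, tolerance = 0.01)
  expect_gt(f$adj_r2, 0.999)
  expect_true(f$criteria_pass)
  expect_equal(f$field_center_cm, 30, tolerance = tr$bin_length_cm)
  # wrapped field across the origin is recentered correctly
  curve_w <- 0.2 + 1.0 * exp(-(circ_dist_cm(x, 2) / 12)^2)
  fw <- fit_gaussian_field(curve_w, tr)
  expect_lt(circ_dist_cm(fw$field_center_cm, 2), tr$bin_length_cm)
  # flat curve fails amplitude criteria
  ff <- fit_gaussian_field(rep(1, 72) + rnorm(72, 0, 1e-4), tr)
  expect_false(ff$criteria_pass)
  # too-wide field fails the half-track bound
  fwide <- fit_gaussian_field(0.1 + exp(-((x - 30) / 22)^2), tr)
  expect_gt(fwide$fwhm_cm, 30.6)
  expect_false(fwide$criteria[2])
  # too-narrow field fails the 2.5 cm bound
  fnar <- fit_gaussian_field(0.1 + exp(-((x - 30) / 1.2)^2), tr)
  expect_false(fnar$criteria[2])
  expect_false(classify_place_cell(list(consistent = TRUE), fnar)$place_cell)
})

test_that("speed score gates on the circular-shuffle percentiles", {
  set.seed(5)
  sp <- abs(rnorm(2000, 50, 30))
  r <- speed_score(sp + rnorm(2000, 0, 1e-6), sp, seed = 1)
  expect_gt(r$speed_score, 0.999)
  expect_true(r$speed_cell); expect_equal(r$speed_sign, "+")
  rn <- speed_score(-sp + rnorm(2000, 0, 1e-6), sp, seed = 1)
  expect_lt(rn$speed_score, -0.999)
  expect_equal(rn$speed_sign, "-")
  expect_error(speed_score(rep(1, 2000), sp), "constant")
  # independent noise passes in roughly 2% of cells (two 1% gates)
  hits <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    speed_score(rnorm(500), rnorm(500, 50, 10), seed = s)$speed_cell
  }, logical(1))
  expect_lt(mean(hits), 0.07)
})

test_that("spatial information matches closed forms and is scale-free", {
  tr <- make_track()
  n <- 72 * 20
  pos <- rep((1:72 - 0.5) * tr$bin_length_cm, 20)
  mv <- rep(TRUE, n)
  # uniform rate, uniform occupancy -> SI 0
  expect_equal(spatial_information(rep(2, n), pos, mv, tr), 0)
  # all spikes in one bin -> log2(72)
  r1 <- as.numeric(pos < tr$bin_length_cm)
  expect_equal(spatial_information(r1, pos, mv, tr), log2(72),
               tolerance = 1e-9)
  # spikes split over 2 of 72 bins -> log2(36)
  r2 <- as.numeric(pos < 2 * tr$bin_length_cm)
  expect_equal(spatial_information(r2, pos, mv, tr), log2(36),
               tolerance = 1e-9)
  # invariant to positive rescaling
  set.seed(8)
  rr <- rexp(n)
  expect_equal(spatial_information(rr, pos, mv, tr),
               spatial_information(7.3 * rr, pos, mv, tr), tolerance = 1e-9)
  # zero total rate -> NA (excluded)
  expect_true(is.na(spatial_information(rep(0, n), pos, mv, tr)))
})

test_that("population classification recovers generated labels", {
  ses <- small_session()
  res <- classified_small()
  truth <- ses$truth$cell_labels
  place_truth <- truth %in% c("place", "conjunctive")
  speed_truth <- truth %in% c("speed", "conjunctive")
  # >= 90% of generated place cells pass the full classifier
  expect_gte(mean(res$place_cell[place_truth]), 0.90)
  # untuned cells essentially never pass
  expect_lte(sum(res$place_cell[truth == "none"]), 1)
  # speed cells detected with the right sign
  sl <- ses$truth$speed_slopes
  det <- res$speed_cell & speed_truth
  expect_gte(mean(res$speed_cell[speed_truth]), 0.6)
  agree <- sign(res$speed_score[det]) ==
    sign(sl[det])
  expect_true(all(agree))
  # field-center recovery from deconvolved-rate tuning curves
  fr <- ses$frames; tr <- ses$track; lk <- attr(fr, "lap_kept")
  idx <- which(place_truth & res$place_cell)
  errs <- fwhm_rel <- numeric(0)
  for (j in idx) {
    tc <- spatial_tuning_curves(ses$rates[j, ], fr$position_cm, fr$moving,
                                fr$lap_id, tr, lk, dt_s = 0.1)
    f <- fit_gaussian_field(tc$mean_curve, tr)
    if (!f$converged) next
    errs <- c(errs, circ_dist_cm(f$field_center_cm,
                                 ses$truth$field_centers_cm[j]))
    fwhm_rel <- c(fwhm_rel, abs(f$fwhm_cm - 15) / 15)
  }
  expect_gte(mean(floor(errs / tr$bin_length_cm) <= 1), 0.9)
  expect_gte(mean(fwhm_rel <= 0.15), 0.8)
})

test_that("lap-time shuffling yields no place cells", {
  ses <- small_session()
  sh <- lap_time_shuffle(ses$dff, ses$frames$lap_id, seed = 77)
  expect_equal(dim(sh), dim(ses$dff))
  expect_equal(sort(sh[1, ses$frames$lap_id == 1]),
               sort(ses$dff[1, ses$frames$lap_id == 1]))
  res <- classify_cells(sh, NULL, ses$frames, ses$track, seed = 77)
  expect_equal(sum(res$place_cell), 0)
})
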