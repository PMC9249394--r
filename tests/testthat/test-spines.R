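test_that("composite projection registers and weights planes", {
  set.seed(13)
  base <- matrix(0, 64, 64)
  base[28:36, 10:54] <- 1
  base <- EBImage::gblur(base, 2)
  # single plane: identity
  expect_equal(composite_projection(array(base, c(64, 64, 1))), base)
  # identical planes: any plane
  st <- array(rep(base, 5), c(64, 64, 5))
  expect_equal(composite_projection(st), base, tolerance = 1e-6)
  # known integer shifts recovered by registration
  sh <- hippo2p:::shift_matrix(base, 2, -3)
  off <- hippo2p:::register_translation(base, sh)
  expect_equal(off, c(-2, 3), tolerance = 0.2)
  st2 <- simplify2array(list(sh, base, hippo2p:::shift_matrix(base, -1, 2)))
  comp <- composite_projection(st2, center_plane = 2)
  expect_gt(cor(as.numeric(comp), as.numeric(base)), 0.99)
})

test_that("binarization recovers two-level images and rescues faint parts", {
  img <- matrix(10, 80, 80)
  img[30:50, 10:70] <- 100
  m <- enhance_and_binarize(img, highpass_sigma_px = 30,
                            min_object_um2 = 0.5)
  truth <- matrix(FALSE, 80, 80); truth[30:50, 10:70] <- TRUE
  expect_gt(sum(m & truth) / sum(m | truth), 0.9)
  # constant image warns and yields empty mask
  expect_warning(me <- enhance_and_binarize(matrix(5, 40, 40)), "constant")
  expect_false(any(me))
  # faint object rescued by a lower threshold
  img2 <- matrix(0, 80, 120)
  img2[35:45, 10:60] <- 100
  img2[35:45, 80:100] <- 12
  m0 <- enhance_and_binarize(img2, highpass_sigma_px = 30,
                             min_object_um2 = 0.2)
  expect_equal(sum(m0[35:45, 80:100]), 0)
  m1 <- enhance_and_binarize(img2, rescue_thresholds = 0.05,
                             highpass_sigma_px = 30, min_object_um2 = 0.2)
  expect_gt(sum(m1[35:45, 80:100]), 100)
})

test_that("classification thresholds reproduce the published table", {
  rec <- function(neck, len, circ, asp)
    list(neck_length_um = neck, length_um = len, head_circularity = circ,
         aspect_ratio = asp)
  expect_equal(classify_spine(rec(0.1, 0.5, 0.5, 1.2)), "stubby")
  expect_equal(classify_spine(rec(0.3, 1.5, 0.9, 2.0)), "mushroom")
  expect_equal(classify_spine(rec(0.3, 0.75, 0.5, 1.5)), "filopodium")
  expect_equal(classify_spine(rec(0.3, 0.6, 0.5, 1.1)), "thin")
  # precedence: stubby beats filopodium-like aspect rule
  expect_equal(classify_spine(rec(0.1, 0.5, 0.9, 1.2)), "stubby")
  # mushroom checked before filopodium on overlap
  expect_equal(classify_spine(rec(0.3, 0.75, 0.9, 1.5)), "mushroom")
  # unmatched falls back to thin with a flag
  out <- classify_spine(rec(0.3, 1.5, 0.5, 1.1))
  expect_equal(as.character(out), "thin")
  expect_true(isTRUE(attr(out, "fallback")))
  # every record receives exactly one class (partition property)
  set.seed(31)
  for (i in 1:50) {
    cl <- classify_spine(rec(runif(1, 0, 0.6), runif(1, 0.2, 2),
                             runif(1), runif(1, 0.5, 4)))
    expect_true(as.character(cl) %in%
                  c("stubby", "mushroom", "filopodium", "thin"))
  }
})

test_that("synthetic spines classify as their own generated class", {
  rt <- dendrite_roundtrip()
  truth <- rt$sim$truth[order(rt$sim$truth$x_px), ]
  got <- rt$ses$spines[order(rt$ses$spines$arc_pos_um), ]
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$class, truth$class)
  # geometry sanity: mushroom heads round, stubby necks absent
  expect_true(all(got$head_circularity[got$class == "mushroom"] > 0.8))
  expect_true(all(got$neck_length_um[got$class == "stubby"] < 0.2))
  expect_true(all(got$aspect_ratio[got$class == "filopodium"] > 1.3))
  # blob below the area threshold is excluded
  few <- analyze_dendrite(rt$sim$mask, min_area_um2 = 10)
  expect_equal(nrow(few$spines), 0)
})

test_that("spine density follows the section formula", {
  rt <- dendrite_roundtrip()
  den <- spine_density(rt$ses)
  expect_equal(den$total_per_10um,
               nrow(rt$ses$spines) / rt$ses$dendrite_length_um * 10)
  expect_equal(sum(den$per_class_per_10um), den$total_per_10um)
  # worked example: 21 spines on a 2000 px skeleton at 52/760 um/px
  s <- structure(list(dendrite_length_um = 2000 * 52 / 760,
                      spines = data.frame(class = rep("thin", 21))),
                 class = "dendrite_session")
  expect_equal(spine_density(s)$total_per_10um, 21 / 136.8 * 10,
               tolerance = 1e-3)
})

test_that("cross-day matching and ledger reproduce constructed events", {
  a <- data.frame(id = 1:5, arc_pos_um = c(2, 5, 9, 14, 20),
                  class = c("thin", "stubby", "mushroom", "thin", "stubby"))
  # identical sessions: nothing added or subtracted
  m <- match_spines_across_days(a, a)
  expect_equal(length(m$added_ids), 0)
  expect_equal(length(m$subtracted_ids), 0)
  # remove 3 known spines
  b <- a[c(1, 4), ]
  m2 <- match_spines_across_days(a, b)
  expect_equal(sort(m2$subtracted_ids), c(2, 3, 5))
  expect_equal(length(m2$added_ids), 0)
  # ledger arithmetic: 20 originals, 15 survivors -> 75%
  t1 <- data.frame(id = 1:20, arc_pos_um = seq(2, 40, by = 2),
                   class = rep("thin", 20))
  t2 <- t1[1:15, ]
  led <- build_turnover_ledger(list(t1, t2))
  sv <- survival_fraction(led)
  expect_equal(sv$survival_pct, c(100, 75))
  # turnover: 3 added on mean total 20 -> 15%
  t3 <- rbind(t2, data.frame(id = 30:32, arc_pos_um = c(41, 43, 45),
                             class = rep("mushroom", 3)))
  led2 <- build_turnover_ledger(list(t1, t2, t3))
  ts <- turnover_stats(led2)
  expect_equal(ts$pct_subtracted[1], 5 / 17.5 * 100)
  expect_equal(ts$pct_added[2], 3 / ((15 + 18) / 2) * 100)
  expect_equal(ts$share_mushroom[2], 1)
  # no turnover: 0% with divide-by-zero guard on shares
  led3 <- build_turnover_ledger(list(t1, t1))
  ts3 <- turnover_stats(led3)
  expect_equal(ts3$pct_added, 0)
  expect_true(all(ts3[1, grep("share_", names(ts3))] == 0))
  # registration check fails on disjoint shafts
  sk1 <- matrix(FALSE, 40, 40); sk1[10, 5:35] <- TRUE
  sk2 <- matrix(FALSE, 40, 40); sk2[30, 5:35] <- TRUE
  expect_error(match_spines_across_days(a, a, skeleton_a = sk1,
                                        skeleton_b = sk2), "unregistered")
})

test_that("noiseless multi-day pipeline recovers the true ledger exactly", {
  spec <- sim_dendrite_spec(seed = 8, n_spines_per_class = c(4, 4, 4, 4),
                            image_shape_px = c(220, 680))
  tsr <- simulate_dendrite_timeseries(spec, days = 5,
                                      daily_add_frac = 0.1,
                                      daily_sub_frac = 0.1)
  tables <- lapply(tsr$masks, function(m)
    analyze_dendrite(m, min_area_um2 = 0.05)$spines)
  led <- build_turnover_ledger(tables)
  expect_equal(unname(led$counts), vapply(tsr$truth, nrow, numeric(1)))
  for (d in 1:4) {
    expect_equal(led$pairs[[d]]$added, length(tsr$events[[d]]$added))
    expect_equal(led$pairs[[d]]$subtracted,
                 length(tsr$events[[d]]$subtracted))
  }
  # conservation: N(t+1) = N(t) + added - subtracted
  for (d in 1:4)
    expect_equal(led$counts[d + 1],
                 led$counts[d] + led$pairs[[d]]$added -
                   led$pairs[[d]]$subtracted)
  # survival matches ground truth and is non-increasing
  orig <- tsr$truth[[1]]$id
  true_surv <- vapply(1:5, function(d)
    mean(orig %in% tsr$truth[[d]]$id) * 100, numeric(1))
  sv <- survival_fraction(led)
  expect_equal(sv$survival_pct, true_surv)
  expect_true(all(diff(sv$survival_pct) <= 0))
  # zero-turnover series keeps survival at 100%
  tsr0 <- simulate_dendrite_timeseries(sim_dendrite_spec(seed = 2),
                                       days = 3, daily_add_frac = 0,
                                       daily_sub_frac = 0)
  led0 <- build_turnover_ledger(lapply(tsr0$truth, identity))
  expect_true(all(survival_fraction(led0)$survival_pct == 100))
})
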