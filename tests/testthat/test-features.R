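test_that("curve typing reproduces the worked examples", {
  expect_equal(classify_voxel_curve(100, 220, 200), "fast_plateau")
  expect_equal(classify_voxel_curve(100, 110, 300), "excluded")
  expect_equal(classify_voxel_curve(100, 140, 160), "slow_persistent")
})

test_that("curve typing honours the inclusive boundary ties", {
  expect_equal(classify_voxel_curve(100, 133, 133), "slow_plateau")  # 33% in
  expect_equal(classify_voxel_curve(100, 150, 150), "slow_plateau")  # 50% slow
  expect_equal(classify_voxel_curve(100, 200, 200), "medium_plateau") # 100% medium
  expect_equal(classify_voxel_curve(100, 201, 201), "fast_plateau")
  expect_equal(classify_voxel_curve(100, 200, 220), "medium_plateau") # +10% plateau
  expect_equal(classify_voxel_curve(100, 200, 180), "medium_plateau") # -10% plateau
  expect_equal(classify_voxel_curve(100, 200, 221), "medium_persistent")
  expect_equal(classify_voxel_curve(100, 200, 179), "medium_washout")
  expect_equal(classify_voxel_curve(100, 132.9, 200), "excluded")
  expect_error(classify_voxel_curve(0, 100, 100), "invalid voxel")
})

# three-voxel series with prescribed (pre, early, delayed) per voxel
three_voxel_series <- function(triples, protocol = dce_protocol()) {
  n <- nrow(triples)
  series <- array(0, c(n, 1, 1, protocol$n_timepoints))
  for (i in seq_len(n)) {
    series[i, 1, 1, ] <- triples[i, 2]                  # fill with early
    series[i, 1, 1, 1] <- triples[i, 1]
    series[i, 1, 1, protocol$delayed_index + 1] <- triples[i, 3]
  }
  series
}

test_that("subvolume percentages match a hand count and the marginals agree", {
  p <- dce_protocol()
  tr <- rbind(c(100, 140, 160),   # slow_persistent
              c(100, 250, 200),   # fast_washout
              c(100, 250, 200))   # fast_washout
  series <- three_voxel_series(tr, p)
  mask <- as_lesion_mask(array(TRUE, c(3, 1, 1)))
  d <- curve_type_distribution(series, mask, p)
  expect_equal(unname(d$cells["slow_persistent"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(d$cells["fast_washout"]), 200 / 3, tolerance = 1e-9)
  expect_equal(sum(d$cells), 100, tolerance = 1e-6)
  expect_equal(sum(d$overall), 100, tolerance = 1e-6)
  # marginals are exactly the sums over initial bands
  for (del in c("washout", "plateau", "persistent"))
    expect_equal(unname(d$overall[del]),
                 sum(d$cells[grepl(paste0("_", del, "$"), names(d$cells))]),
                 tolerance = 1e-9)
  # uniform lesion: one cell holds 100%
  d2 <- curve_type_distribution(three_voxel_series(rbind(c(100, 250, 200))),
                                as_lesion_mask(array(TRUE, c(1, 1, 1))), p)
  expect_equal(unname(d2$cells["fast_washout"]), 100)
  expect_equal(unname(d2$overall["washout"]), 100)
  # all excluded -> error
  expect_error(
    curve_type_distribution(three_voxel_series(rbind(c(100, 110, 100))),
                            as_lesion_mask(array(TRUE, c(1, 1, 1))), p),
    "non-enhancing lesion")
})

test_that("the mean curve averages threshold-passing voxels", {
  p <- dce_protocol()
  a <- c(100, 200, 190, 185, 180, 175, 170, 165)
  b <- c(100, 160, 165, 170, 175, 180, 185, 190)
  series <- array(0, c(2, 1, 1, 8))
  series[1, 1, 1, ] <- a; series[2, 1, 1, ] <- b
  mask <- as_lesion_mask(array(TRUE, c(2, 1, 1)))
  expect_equal(mean_curve(series, mask, p), (a + b) / 2)
  single <- as_lesion_mask(array(c(TRUE, FALSE), c(2, 1, 1)))
  expect_equal(mean_curve(series, single, p), a)
  # homogeneous noise-free lesion equals the forward-model curve
  les <- make_uniform_lesion(ktrans = 0.25, ve = 0.35, alpha = 8)
  tm <- frame_times(les$protocol, "minutes")
  model <- 100 * (1 + 8 * tofts_concentration(tm, 0.25, 0.35))
  mc <- mean_curve(les, as_lesion_mask(les$mask))
  expect_equal(mc, model, tolerance = 1e-9)
})

test_that("representative clusters are found by exhaustive-scan logic", {
  p <- dce_protocol()
  # homogeneous slab: every cluster curve equals the voxel curve
  kt <- array(0.25, c(7, 7, 3)); ve <- array(0.35, c(7, 7, 3))
  series <- make_phantom_series(kt, ve)
  mask <- as_lesion_mask(array(TRUE, c(7, 7, 3)))
  cl <- find_representative_clusters(series, mask, p)
  tm <- frame_times(p, "minutes")
  vox <- 100 * (1 + 8 * tofts_concentration(tm, 0.25, 0.35))
  expect_equal(cl$max_washin, vox, tolerance = 1e-9)
  expect_equal(cl$max_washout, (vox[-1] - vox[1]) / vox[1], tolerance = 1e-9)
  expect_false(cl$fallback)

  # doubled-ktrans 3x3 patch attracts the max wash-in cluster
  kt2 <- kt; kt2[3:5, 3:5, 2] <- 0.5
  cl2 <- find_representative_clusters(make_phantom_series(kt2, ve), mask, p)
  expect_equal(cl2$centers$max_washin, c(4L, 4L, 2L))

  # washout patch (high kep) vs persistent patch
  kt3 <- array(0.1, c(9, 9, 1)); ve3 <- array(0.8, c(9, 9, 1))
  kt3[2:4, 2:4, 1] <- 1.8; ve3[2:4, 2:4, 1] <- 0.1   # kep = 18: washes out
  kt3[6:8, 6:8, 1] <- 0.3; ve3[6:8, 6:8, 1] <- 0.8   # persistent
  cl3 <- find_representative_clusters(make_phantom_series(kt3, ve3),
                                      as_lesion_mask(array(TRUE, c(9, 9, 1))), p)
  expect_equal(cl3$centers$max_washout, c(3L, 3L, 1L))

  # no complete in-plane 3x3 neighborhood -> single-voxel fallback
  thin <- as_lesion_mask(array(TRUE, c(2, 7, 3)))
  cl4 <- find_representative_clusters(make_phantom_series(
    array(0.25, c(2, 7, 3)), array(0.35, c(2, 7, 3))), thin, p)
  expect_true(cl4$fallback)
})

test_that("scaling up postcontrast signal cannot lower the wash-in winner", {
  p <- dce_protocol()
  set.seed(12)
  kt <- array(runif(7 * 7 * 2, 0.1, 0.4), c(7, 7, 2))
  ve <- array(runif(7 * 7 * 2, 0.2, 0.6), c(7, 7, 2))
  series <- make_phantom_series(kt, ve)
  mask <- as_lesion_mask(array(TRUE, c(7, 7, 2)))
  cl <- find_representative_clusters(series, mask, p)
  up <- series
  up[, , , -1] <- up[, , , -1] * 1.5    # fixed precontrast, higher post
  cl_up <- find_representative_clusters(up, mask, p)
  wi <- function(x) (x$max_washin[2] - x$max_washin[1]) / x$max_washin[1]
  expect_gte(wi(cl_up), wi(cl))
})

test_that("wash-out rates follow the printed two-reference definition", {
  r <- washout_rates(list(
    mean = c(100, 180, 190, rep(150, 5)),
    max_washin = c(100, 180, 190, 150, 150, 150, 150, 150),
    max_washout = c(0.8, 0.9, rep(0.5, 5)),
    max_washin_washout = c(0.8, 0.9, rep(0.5, 5))))
  expect_equal(unname(r["washrate_max_washout.ref1"]), 0.8 - 0.5)
  expect_equal(unname(r["washrate_max_washout.ref2"]), 0.9 - 0.5)
  # flat relative curve -> zero rates
  r0 <- washout_rates(list(mean = rep(100, 8), max_washin = rep(100, 8),
                           max_washout = rep(0.4, 7),
                           max_washin_washout = rep(0.4, 7)))
  expect_equal(unname(r0), rep(0, 8))
  # monotone increasing curve -> both rates negative (persistent)
  rup <- washout_rates(list(mean = 100 + 10 * (0:7),
                            max_washin = 100 + 10 * (0:7),
                            max_washout = seq(0.1, 0.7, by = 0.1),
                            max_washin_washout = seq(0.1, 0.7, by = 0.1)))
  expect_true(all(rup < 0))
})

test_that("pharmacokinetic percentiles match the sort-and-interpolate oracle", {
  pk <- data.frame(iauc = 1:100, ktrans = (1:100) / 100, ve = (100:1) / 200,
                   fit_ok = TRUE)
  f <- pk_histogram_features(pk)
  expect_length(f, 36)
  probs <- c(.10, .20, .25, .30, .40, .50, .60, .70, .75, .80, .90)
  for (i in seq_along(probs))
    expect_equal(unname(f[paste0("iauc_p", round(100 * probs[i]))]),
                 oracle_percentile(1:100, probs[i]))
  expect_equal(unname(f["iauc_iqr"]),
               oracle_percentile(1:100, .75) - oracle_percentile(1:100, .25))
  # constant map
  fc <- pk_histogram_features(data.frame(iauc = rep(3, 9), ktrans = rep(1, 9),
                                         ve = rep(0.5, 9), fit_ok = TRUE))
  expect_true(all(fc[grep("^iauc_p", names(fc))] == 3))
  expect_equal(unname(fc["iauc_iqr"]), 0)
  # order invariance
  shuffled <- pk[sample(nrow(pk)), ]
  expect_equal(pk_histogram_features(shuffled), f)
  # nondecreasing percentile sequences
  expect_true(all(diff(f[grep("^ktrans_p", names(f))]) >= 0))
  expect_error(pk_histogram_features(data.frame(iauc = 1, ktrans = 1,
                                                ve = 1, fit_ok = FALSE)),
               "no pharmacokinetic data")
})

test_that("the assembled vector has exactly 86 features in the fixed order", {
  les <- make_uniform_lesion(semi_axes = c(4, 4, 4))
  mask <- segment_lesion(les, les$seed_voxel)
  fx <- extract_lesion_features(les, mask)
  v <- fx$features
  expect_length(v, 86)
  expect_identical(names(v), names(breastdce:::example_feature_names()))
  counts <- c(mean_si = 8, maxwi_si = 8, maxwo_rel = 7, maxwiwo_rel = 7,
              subvol = 9, washrate = 8, overall = 3)
  for (g in names(counts))
    expect_equal(sum(startsWith(names(v), g)), unname(counts[g]))
  expect_equal(sum(grepl("_p[0-9]+$", names(v))), 33)
  expect_equal(sum(endsWith(names(v), "_iqr")), 3)
  expect_true(all(is.finite(v)))
  expect_equal(sum(v[startsWith(names(v), "subvol")]), 100, tolerance = 1e-6)
  # determinism: identical lesions give identical vectors
  fx2 <- extract_lesion_features(les, mask)
  expect_identical(fx$features, fx2$features)
  expect_error(assemble_feature_vector(NULL, NULL, NULL, NULL, NULL),
               "missing feature group")
})

test_that("the feature dictionary covers all 86 features", {
  d <- feature_dictionary()
  expect_equal(nrow(d), 86)
  expect_identical(d$feature, names(breastdce:::example_feature_names()))
})
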