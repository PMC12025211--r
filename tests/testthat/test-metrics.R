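test_that("confusion counts match brute-force enumeration", {
  # hand case: pred (1,1,0,0) vs true (1,0,1,0)
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), 2)
  expect_equal(unname(cc["1", ]), c(1L, 1L, 1L, 1L))
  set.seed(10)
  for (rep in 1:20) {
    p <- random_mask(); t <- random_mask()
    cc <- confusion(p, t, 5)
    for (k in 0:4)
      expect_equal(unname(cc[as.character(k), ]),
                   unname(bf_confusion_class(p, t, k)))
    expect_true(all(rowSums(cc) == length(p)))
  }
  expect_error(confusion(c(0, 1), c(0, 5), 2), "range")
  expect_error(confusion(c(0, 1, 0), c(0, 1), 2), "shape")
})

test_that("overlap scores match hand arithmetic and the dice identity", {
  cc <- rbind(c(TP = 2, FP = 2, FN = 2, TN = 10))
  expect_equal(unname(jaccard(cc)), 1 / 3)
  expect_equal(unname(dice(cc)), 0.5)
  # perfect overlap
  p <- random_mask()
  cc2 <- confusion(p, p, 5)
  expect_equal(unname(jaccard(cc2)), rep(1, 5))
  expect_equal(unname(dice(cc2)), rep(1, 5))
  expect_equal(unname(sensitivity(cc2)), rep(1, 5))
  expect_equal(unname(specificity(cc2)), rep(1, 5))
  set.seed(11)
  for (rep in 1:20) {
    cc3 <- confusion(random_mask(), random_mask(), 5)
    J <- jaccard(cc3)
    expect_equal(dice(cc3), 2 * J / (1 + J), tolerance = 1e-12)
    expect_true(all(J <= dice(cc3) + 1e-15))
  }
})

test_that("mean surface distance matches brute-force nearest-point search", {
  a <- matrix(0L, 8, 8); a[2, 2] <- 1L
  b <- matrix(0L, 8, 8); b[2, 5] <- 1L
  expect_equal(mean_surface_distance(a, b, 1, 1), 3)
  expect_equal(mean_surface_distance(a, a, 1, 1), 0)
  expect_equal(mean_surface_distance(a, b, 1, 0.5), 1.5)
  # directed asymmetry and symmetric mode
  set.seed(12)
  for (rep in 1:10) {
    p <- random_mask(12, 3); t <- random_mask(12, 3)
    for (k in 1:2) {
      ab <- mean_surface_distance(p, t, k, 1, "directed")
      ba <- mean_surface_distance(t, p, k, 1, "directed")
      sym <- mean_surface_distance(p, t, k, 1, "symmetric")
      expect_equal(ab, bf_msd(p, t, k), tolerance = 1e-12)
      expect_equal(sym, (ab + ba) / 2, tolerance = 1e-12)
    }
  }
  # empty boundary -> undefined, not zero
  empty <- matrix(0L, 8, 8)
  expect_true(is.na(mean_surface_distance(empty, b, 1, 1)))
})

test_that("slice error is the signed index difference", {
  expect_equal(slice_error(57, 55), 2)
  expect_equal(slice_error(55, 55), 0)
  expect_equal(abs_slice_error(53, 55), 2)
})

test_that("Bland-Altman limits use the n-1 standard deviation", {
  ba <- bland_altman(c(10, 12, 10, 11), c(10, 11, 11, 11))
  # differences {0, 1, -1, 0}
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ba$upper_limit, 1.96 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ba$fraction_within, 1)
  # all-equal differences: limits collapse, strict fraction is 0
  ba0 <- bland_altman(c(5, 6, 7), c(4, 5, 6))
  expect_equal(ba0$lower_limit, ba0$upper_limit)
  expect_equal(ba0$fraction_within, 0)
  # translation shifts the mean, not the width
  ba1 <- bland_altman(c(10, 12, 10, 11) + 3, c(10, 11, 11, 11))
  expect_equal(ba1$mean_difference, 3)
  expect_equal(ba1$upper_limit - ba1$lower_limit,
               ba$upper_limit - ba$lower_limit, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "2 pairs")
})

test_that("tissue area applies the squared resize correction", {
  mask <- matrix(0L, 256, 256)
  mask[1:40, 1:25] <- 1L  # 1000 pixels
  expect_equal(tissue_area(mask, 1, 0.9, native_size = 512), 3240)
  expect_equal(tissue_area(mask, 1, 0.9), 1000 * 0.81)
  expect_equal(tissue_area(mask, 2, 0.9), 0)
})

test_that("area is approximately resize-invariant once corrected", {
  pp <- phantom_params(image_size = 64, slices_per_patient = 4)
  p <- generate_patient(pp, 77)
  mk <- p$masks[[2]]
  half <- resize_mask(mk, 32)
  for (k in 1:3) {
    a_native <- tissue_area(mk, k, p$pixel_spacing_mm)
    a_half <- tissue_area(half, k, p$pixel_spacing_mm, native_size = 64)
    if (a_native == 0) next
    expect_lt(abs(a_half - a_native) / a_native, 0.1)
  }
})

test_that("r_squared matches the hand least-squares value", {
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.9642857,
               tolerance = 1e-6)
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(r_squared(1:5 + 10, 1:5), 1)
  expect_error(r_squared(1:3, c(2, 2, 2)), "variance")
  expect_equal(r_squared(c(3, 3, 3), 1:3), 0)
})

test_that("seg_metrics aggregates the per-class battery", {
  set.seed(13)
  p <- random_mask(); t <- random_mask()
  sm <- seg_metrics(p, t, pixel_spacing_mm = 2, classes = 1:4, n_classes = 5)
  expect_equal(nrow(sm$per_class), 4)
  cc <- confusion(p, t, 5)
  expect_equal(sm$per_class$dice, unname(dice(cc)[as.character(1:4)]))
  expect_equal(unname(sm$macro["dice"]), mean(sm$per_class$dice))
  expect_equal(sm$per_class$msd[1], bf_msd(p, t, 1, spacing = 2),
               tolerance = 1e-12)
})
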