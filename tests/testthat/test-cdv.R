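test_that("augmentation plans implement the target-ratio arithmetic", {
  # the clinical-scale imbalance regime: 380 minority vs 10984 majority
  p <- make_augmentation_plan(380, 10984, d_a = 0.20, seed = 1)
  expect_equal(p$target_minority, 2197)      # round(0.20 * 10984)
  expect_equal(p$n_augmented_needed, 1817)
  expect_equal(nrow(p$op_sequence), 1817)
  # d_a = 1 means exact 1:1 balance
  p1 <- make_augmentation_plan(380, 10984, d_a = 1, seed = 1)
  expect_equal(p1$target_minority, 10984)
  # soft failure: target below current minority -> zero augmentations
  p0 <- make_augmentation_plan(500, 1000, d_a = 0.3, seed = 1)
  expect_equal(p0$n_augmented_needed, 0)
  expect_equal(nrow(p0$op_sequence), 0)
  expect_error(make_augmentation_plan(10, 100, d_a = 1.2), "d_a")
  expect_error(make_augmentation_plan(10, 100, d_a = 0), "d_a")
  # determinism and source cycling
  p2 <- make_augmentation_plan(3, 100, d_a = 0.1, seed = 9)
  expect_identical(p2$op_sequence,
                   make_augmentation_plan(3, 100, d_a = 0.1, seed = 9)$op_sequence)
  expect_equal(p2$op_sequence$source_index, rep(1:3, length.out = 7))
  expect_true(all(p2$op_sequence$transform %in%
                    c("rotation", "hflip", "vflip")))
})

test_that("flip transforms are involutions and rotation preserves labels", {
  m <- matrix(1:4 / 4, 2, 2)
  expect_identical(augment_image(augment_image(m, "hflip"), "hflip"), m)
  expect_identical(augment_image(augment_image(m, "vflip"), "vflip"), m)
  expect_equal(augment_image(m, "vflip"), m[2:1, ])
  expect_error(augment_image(m, "zoom"), "unknown transform")
  set.seed(4)
  for (s in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    mask <- matrix(sample(0:4, 32 * 32, TRUE), 32, 32)
    out <- augment_image(img, "rotation", transform_seed = s, mask = mask)
    expect_equal(dim(out$image), dim(img))
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_true(all(out$mask %in% 0:4))
    # deterministic under the transform seed
    out2 <- augment_image(img, "rotation", transform_seed = s, mask = mask)
    expect_identical(out, out2)
  }
})

test_that("segmentation augmentation multiplies the set and keeps originals", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  msks <- lapply(1:3, function(i) matrix(sample(0:4, 64, TRUE), 8, 8))
  aug <- segmentation_augment(imgs, msks, factor = 4, seed = 2)
  expect_length(aug$images, 12)
  expect_identical(aug$images[1:3], imgs)
  expect_identical(aug$masks[1:3], msks)
  expect_equal(sum(aug$is_augmented), 9)
  aug2 <- segmentation_augment(imgs, msks, factor = 4, seed = 2)
  expect_identical(aug, aug2)
  expect_identical(segmentation_augment(imgs, msks, factor = 1, seed = 2)$images,
                   imgs)
})

test_that("class-weight minima follow the task rules", {
  f <- c(0.0334, 0.9666)
  cw <- compute_class_weights(f, task = "detection")
  expect_equal(cw$minima, 1 / sqrt(f), tolerance = 1e-12)
  expect_equal(cw$minima[1], 5.4718, tolerance = 1e-4)
  expect_equal(cw$minima[2], 1.0171, tolerance = 1e-4)
  # equal binary frequencies + d_c at minima -> equal unit weights
  cweq <- compute_class_weights(c(0.5, 0.5), task = "detection")
  expect_equal(unname(cweq$weights), c(1, 1))
  # weights respect minima up to the common rescale factor
  d_c <- c(2, 9)
  cw2 <- compute_class_weights(f, d_c = d_c, task = "detection")
  scale <- cw2$raw_weights / cw2$weights
  expect_equal(unname(scale[1]), unname(scale[2]), tolerance = 1e-12)
  expect_true(all(cw2$raw_weights >= pmax(cw2$minima, d_c) - 1e-12))
  expect_equal(mean(cw2$weights), 1, tolerance = 1e-12)
  # segmentation: printed pixel-ratio rule vs the inverse variant
  fs <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  expect_equal(compute_class_weights(fs, task = "segmentation")$minima, fs)
  expect_equal(compute_class_weights(fs, task = "segmentation",
                                     min_rule = "inverse_pixel_ratio")$minima,
               1 / fs)
  expect_error(compute_class_weights(c(a = 0, b = 1), task = "detection"), "'a'")
  expect_error(compute_class_weights(c(0.5, 0.4), task = "detection"), "sum")
})

test_that("weighted cross-entropy matches hand values and is linear in w", {
  # perfect one-hot predictions give zero loss
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(weighted_cross_entropy(p, c(0, 1), c(1, 1)), 0,
               tolerance = 1e-10)
  # two samples with p_true = 0.5 and unit weights -> ln 2
  p2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(weighted_cross_entropy(p2, c(0, 1), c(1, 1)), log(2),
               tolerance = 1e-12)
  set.seed(6)
  pr <- matrix(runif(30), 10, 3)
  pr <- pr / rowSums(pr)
  y <- sample(0:2, 10, TRUE)
  w <- runif(3, 0.5, 2)
  expect_equal(weighted_cross_entropy(pr, y, 2 * w),
               2 * weighted_cross_entropy(pr, y, w), tolerance = 1e-12)
  # uniform weights reduce to unweighted cross-entropy
  ce <- mean(-log(pr[cbind(1:10, y + 1)]))
  expect_equal(weighted_cross_entropy(pr, y, c(1, 1, 1)), ce,
               tolerance = 1e-12)
  expect_error(weighted_cross_entropy(pr, c(y[-1], 5), w), "range")
  expect_error(weighted_cross_entropy(pr * 2, y, w), "sum to 1")
})
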