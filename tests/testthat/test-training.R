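test_that("fold splitting partitions patients with balanced sizes", {
  cohort <- tiny_phantom(15, seed = 30, image_size = 16, slices = 4)
  folds <- split_folds(cohort, k = 5, seed = 2)
  expect_equal(sort(unique(folds$fold)), 1:5)
  expect_equal(as.vector(table(folds$fold)), rep(3L, 5))
  # test folds over all rounds cover the cohort exactly once
  seen <- unlist(lapply(1:5, function(f) fold_patients(folds, f)))
  expect_setequal(seen, vapply(cohort, `[[`, "", "patient_id"))
  expect_equal(anyDuplicated(seen), 0)
  # 7 patients in 5 folds -> sizes {2,2,1,1,1}
  f7 <- split_folds(tiny_phantom(7, seed = 1, image_size = 16, slices = 4),
                    k = 5, seed = 9)
  expect_equal(sort(as.vector(table(f7$fold)), decreasing = TRUE),
               c(2L, 2L, 1L, 1L, 1L))
  expect_error(split_folds(tiny_phantom(3, seed = 1, image_size = 16,
                                        slices = 4), k = 5), "fewer")
  expect_identical(as.data.frame(split_folds(cohort, 5, seed = 2)),
                   as.data.frame(split_folds(cohort, 5, seed = 2)))
})

test_that("detection datasets hit the planned class counts with no leakage", {
  cohort <- tiny_phantom(6, seed = 31, image_size = 32, slices = 10)
  folds <- split_folds(cohort, k = 3, seed = 1)
  train_ids <- fold_patients(folds, 1, test = FALSE)
  test_ids <- fold_patients(folds, 1, test = TRUE)
  cts <- detection_class_counts(cohort, train_ids)
  plan <- make_augmentation_plan(cts[["n_minority"]], cts[["n_majority"]],
                                 d_a = 0.5, seed = 4)
  ds <- build_detection_dataset(cohort, train_ids, plan, input_size = 16)
  expect_equal(sum(ds$labels == 1), max(cts[["n_minority"]],
                                        plan$target_minority))
  expect_equal(sum(ds$labels == 0), cts[["n_majority"]])
  expect_false(any(stats::na.omit(ds$patient_ids) %in% test_ids))
  # no plan -> preprocessed originals only
  ds0 <- build_detection_dataset(cohort, train_ids, input_size = 16)
  expect_equal(dim(ds0$images)[3], sum(cts))
  # plan built from the wrong patients is rejected
  expect_error(build_detection_dataset(cohort, test_ids, plan,
                                       input_size = 16), "counts")
})

test_that("segmentation datasets take only L3 slices with paired transforms", {
  cohort <- tiny_phantom(4, seed = 32, image_size = 32, slices = 10, l3 = 0.2)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  n_l3 <- sum(unlist(lapply(cohort, `[[`, "l3_flags")))
  ds <- build_segmentation_dataset(cohort, ids, factor = 4, seed = 5,
                                   input_size = 16)
  expect_equal(dim(ds$images)[3], 4 * n_l3)
  expect_equal(sum(!ds$is_augmented), n_l3)
  expect_true(all(ds$masks %in% 0:4))
  ds2 <- build_segmentation_dataset(cohort, ids, factor = 4, seed = 5,
                                    input_size = 16)
  expect_identical(ds, ds2)
  # factor 1 keeps originals only
  ds1 <- build_segmentation_dataset(cohort, ids, factor = 1, input_size = 16)
  expect_equal(dim(ds1$images)[3], n_l3)
  # a missing mask on an L3 slice is an error
  broken <- cohort
  broken[[1]]$masks[which(broken[[1]]$l3_flags)[1]] <- list(NULL)
  expect_error(build_segmentation_dataset(broken, ids[1], input_size = 16),
               "missing mask")
})

test_that("reference trainers consume every hyperparameter design variable", {
  cohort <- tiny_phantom(3, seed = 33, image_size = 32, slices = 8, l3 = 0.2)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  ds <- build_detection_dataset(cohort, ids, input_size = 16)
  tr <- reference_detector(16, 2)
  w <- c(1, 1)
  d <- midrange_design()
  d$epochs <- 5L
  h5 <- tr$fit(ds$images, ds$labels, d, w, seed = 1)
  d$epochs <- 10L
  h10 <- tr$fit(ds$images, ds$labels, d, w, seed = 1)
  steps_per_epoch <- ceiling(dim(ds$images)[3] / d$batch_size)
  expect_equal(h5$meta$n_steps, 5 * steps_per_epoch)
  expect_equal(h10$meta$n_steps, 10 * steps_per_epoch)
  # gradient clipping bounds the recorded post-clip norms
  d$gradient_threshold <- 1L
  hc <- tr$fit(ds$images, ds$labels, d, w, seed = 1)
  expect_true(all(hc$meta$grad_norms <= 1 + 1e-6))
  # designs outside the search bounds are rejected
  bad <- midrange_design(); bad$initial_learning_rate <- 1
  expect_error(tr$fit(ds$images, ds$labels, bad, w, seed = 1), "outside")
})

test_that("training is deterministic and predictions are proper probabilities", {
  cohort <- tiny_phantom(3, seed = 34, image_size = 32, slices = 8, l3 = 0.2)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  ds <- build_detection_dataset(cohort, ids, input_size = 16)
  tr <- reference_detector(16, 2)
  d <- midrange_design(); d$epochs <- 5L
  h1 <- tr$fit(ds$images, ds$labels, d, c(1, 3), seed = 9)
  h2 <- tr$fit(ds$images, ds$labels, d, c(1, 3), seed = 9)
  expect_identical(h1$model$c1W, h2$model$c1W)
  expect_identical(h1$meta$losses, h2$meta$losses)
  p1 <- tr$predict(h1, ds$images)
  p2 <- tr$predict(h2, ds$images)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-6)
  # segmentation counterpart
  sds <- build_segmentation_dataset(cohort, ids, factor = 2, seed = 2,
                                    input_size = 16)
  trs <- reference_segmenter(16, 2)
  s1 <- trs$fit(sds$images, sds$masks, d, rep(1, 5), seed = 9)
  s2 <- trs$fit(sds$images, sds$masks, d, rep(1, 5), seed = 9)
  expect_identical(s1$model$c4W, s2$model$c4W)
  pm <- trs$predict(s1, sds$images[, , 1:2, drop = FALSE])
  expect_equal(dim(pm), c(16, 16, 5, 2))
  sums <- apply(pm, c(1, 2, 4), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-5)
})

test_that("the detector separates a linearly separable toy set", {
  set.seed(35)
  n <- 60
  imgs <- array(0, dim = c(16, 16, n))
  labels <- rep(0:1, each = n / 2)
  for (i in seq_len(n))
    imgs[, , i] <- matrix(runif(256, 0, 0.3) + 0.6 * labels[i], 16, 16)
  tr <- reference_detector(16, 4)
  d <- midrange_design()
  d$initial_learning_rate <- 1e-2
  d$epochs <- 20L
  d$batch_size <- 10L
  h <- tr$fit(imgs, labels, d, c(1, 1), seed = 2)
  pr <- tr$predict(h, imgs)
  pred <- as.integer(pr[, 2] > pr[, 1])
  cc <- confusion(pred, labels, 2)
  expect_equal(unname(dice(cc)["1"]), 1)  # F1 = 1
})

test_that("predict_l3_slice takes the argmax with low-index ties", {
  cohort <- tiny_phantom(2, seed = 36, image_size = 32, slices = 8, l3 = 0.2)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  ds <- build_detection_dataset(cohort, ids, input_size = 16)
  tr <- reference_detector(16, 2)
  d <- midrange_design(); d$epochs <- 5L
  h <- tr$fit(ds$images, ds$labels, d, c(1, 4), seed = 3)
  pr <- predict_l3_slice(tr, h, cohort[[1]])
  expect_equal(pr$index, which.max(pr$p_l3))
  expect_length(pr$p_l3, 8)
  expect_error(predict_l3_slice(tr, h, list(slices = list())), "empty")
})
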