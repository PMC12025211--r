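#' Patient-level cross-validation folds
#'
#' Patients are shuffled deterministically by `seed` and dealt round-robin
#' into `k` folds, so fold sizes differ by at most one and all slices of a
#' patient share one fold (no patient leakage).
#'
#' @param cohort a `ct_cohort` (or list of `patient_volume`s).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return a `fold_assignment`: data frame with `patient_id`, `fold`, plus
#'   attributes `k`, `seed`.
#' @export
split_folds <- function(cohort, k = 5L, seed = 1L) {
  ids <- vapply(cohort, `[[`, "", "patient_id")
  if (length(ids) < k) stop("fewer patients than folds")
  perm <- with_seed(seed, sample(ids))
  out <- data.frame(patient_id = perm,
                    fold = rep(seq_len(k), length.out = length(perm)),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$patient_id, ids)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fold_assignment", "data.frame"), k = k, seed = seed)
}

fold_patients <- function(folds, fold, test = TRUE) {
  sel <- if (test) folds$fold == fold else folds$fold != fold
  folds$patient_id[sel]
}

#' Slice class counts over a set of patients
#'
#' @param cohort a `ct_cohort`.
#' @param patient_ids patients to include.
#' @return named vector `c(n_majority, n_minority)` of non-L3 and L3 slice
#'   counts.
#' @export
detection_class_counts <- function(cohort, patient_ids) {
  flags <- unlist(lapply(cohort, function(p)
    if (p$patient_id %in% patient_ids) p$l3_flags else logical(0)))
  c(n_majority = sum(!flags), n_minority = sum(flags))
}

.preprocess_stack <- function(slices, input_size, window, stretch) {
  n <- length(slices)
  out <- array(0, dim = c(input_size, input_size, n))
  for (i in seq_len(n)) {
    x <- apply_hu_window(slices[[i]], window[1], window[2])
    x <- histogram_stretch(x, stretch[1], stretch[2])
    out[, , i] <- resize_image(x, input_size)
  }
  out
}

#' Build the (optionally augmented) L3-detection training set
#'
#' Slices from the selected patients are preprocessed
#' (window, stretch, resize) and labelled 0 = non-L3, 1 = L3. If an
#' [make_augmentation_plan()] is supplied, the plan is executed on the
#' preprocessed minority slices, raising the minority count to exactly
#' `max(n_minority, target_minority)`; originals are always retained.
#'
#' @param cohort a `ct_cohort`.
#' @param patient_ids patients whose slices enter the set (use the training
#'   folds only; the plan must have been built from the same patients).
#' @param plan optional `augmentation_plan`.
#' @param input_size network input side length.
#' @param window,stretch preprocessing parameters.
#' @param angle_range rotation range for augmented samples (degrees).
#' @return list with `images` (array `input_size x input_size x N`),
#'   `labels` (0/1), `patient_ids` (per sample; `NA` for augmented
#'   samples), `plan`.
#' @export
build_detection_dataset <- function(cohort, patient_ids, plan = NULL,
                                    input_size = 16L,
                                    window = c(-190, 150),
                                    stretch = c(1, 99),
                                    angle_range = 15) {
  sel <- Filter(function(p) p$patient_id %in% patient_ids, cohort)
  if (length(sel) == 0) stop("no patients selected")
  slices <- unlist(lapply(sel, `[[`, "slices"), recursive = FALSE)
  labels <- as.integer(unlist(lapply(sel, `[[`, "l3_flags")))
  pids <- unlist(lapply(sel, function(p) rep(p$patient_id, length(p$slices))))
  images <- .preprocess_stack(slices, input_size, window, stretch)
  if (!is.null(plan) && plan$n_augmented_needed > 0) {
    if (plan$n_minority != sum(labels == 1L) ||
        plan$n_majority != sum(labels == 0L))
      stop("augmentation plan class counts do not match the selected patients")
    minority_idx <- which(labels == 1L)
    ops <- plan$op_sequence
    extra <- array(0, dim = c(input_size, input_size, nrow(ops)))
    for (i in seq_len(nrow(ops))) {
      src <- images[, , minority_idx[ops$source_index[i]]]
      extra[, , i] <- augment_image(src, ops$transform[i],
                                    ops$transform_seed[i],
                                    angle_range = angle_range)
    }
    images <- array(c(images, extra),
                    dim = c(input_size, input_size, dim(images)[3] + nrow(ops)))
    labels <- c(labels, rep(1L, nrow(ops)))
    pids <- c(pids, rep(NA_character_, nrow(ops)))
  }
  list(images = images, labels = labels, patient_ids = pids, plan = plan)
}

#' Build the tissue-segmentation training set (L3 slices only)
#'
#' Only L3-flagged slices enter; each must carry a mask. Images are
#' preprocessed and masks resized with nearest-neighbour to the same input
#' size; the set is then expanded `factor`-fold with paired
#' image/mask transforms ([segmentation_augment()]).
#'
#' @param cohort a `ct_cohort`.
#' @param patient_ids patients whose L3 slices enter the set.
#' @param factor augmentation multiple (default 4).
#' @param seed augmentation seed.
#' @param input_size network input side length.
#' @param window,stretch preprocessing parameters.
#' @param angle_range rotation range (degrees).
#' @return list with `images` and `masks` (arrays), `patient_ids`,
#'   `is_augmented`.
#' @export
build_segmentation_dataset <- function(cohort, patient_ids, factor = 4L,
                                       seed = 1L, input_size = 32L,
                                       window = c(-190, 150),
                                       stretch = c(1, 99),
                                       angle_range = 15) {
  sel <- Filter(function(p) p$patient_id %in% patient_ids, cohort)
  if (length(sel) == 0) stop("no patients selected")
  images <- list(); masks <- list(); pids <- character(0)
  for (p in sel) {
    for (z in which(p$l3_flags)) {
      if (is.null(p$masks[[z]]))
        stop(sprintf("missing mask on L3 slice %d of patient %s",
                     z, p$patient_id))
      x <- apply_hu_window(p$slices[[z]], window[1], window[2])
      x <- histogram_stretch(x, stretch[1], stretch[2])
      images[[length(images) + 1]] <- resize_image(x, input_size)
      masks[[length(masks) + 1]] <- resize_mask(p$masks[[z]], input_size)
      pids <- c(pids, p$patient_id)
    }
  }
  aug <- segmentation_augment(images, masks, factor = factor, seed = seed,
                              angle_range = angle_range)
  n <- length(aug$images)
  list(images = array(unlist(aug$images), dim = c(input_size, input_size, n)),
       masks = array(as.integer(unlist(aug$masks)),
                     dim = c(input_size, input_size, n)),
       patient_ids = c(pids, rep(NA_character_, n - length(pids))),
       is_augmented = aug$is_augmented)
}

# ---------------------------------------------------------------------------
# trainer contract: an object with $task, $fit(images, labels_or_masks,
# design, weights, seed) -> handle, and $predict(handle, images) ->
# probabilities. Same seed + same inputs => identical predictions.

#' Reference CPU-scale backbones behind the trainer contract
#'
#' `reference_detector()` is a small residual CNN (stem, two residual
#' blocks with identity shortcuts, global average pooling, softmax head)
#' for binary L3 detection; `reference_segmenter()` is a small three-level
#' U-Net (3x3 convolutions, max-pooling, nearest-neighbour upsampling,
#' skip connections) for 5-class tissue segmentation. Both are trained by
#' SGD with momentum and consume every hyperparameter design variable:
#' initial learning rate, L2 regularisation, batch size, global
#' gradient-norm clipping threshold, epochs and momentum, with per-class
#' weighted cross-entropy. Training is bit-deterministic given the seed;
#' per-step post-clipping gradient norms and the optimizer step count are
#' recorded in the handle's `meta`.
#'
#' @param input_size network input side length (detector: even;
#'   segmenter: divisible by 4).
#' @param channels base channel width.
#' @param n_classes segmentation class count (default 5, codes 0-4).
#' @return a `trainer` object: list with `task`, `input_size`, `fit`,
#'   `predict`.
#' @export
reference_detector <- function(input_size = 16L, channels = 4L) {
  force(input_size); force(channels)
  tr <- list(
    task = "detection",
    input_size = as.integer(input_size),
    fit = function(images, labels, design, weights, seed = 1L) {
      w <- if (inherits(weights, "class_weights")) weights$weights else weights
      .check_design(design)
      model <- cpp_det_fit(images, as.integer(labels), design,
                           as.numeric(w), as.integer(channels),
                           as.integer(seed))
      structure(list(backend = "reference_resnet", model = model,
                     design = design,
                     meta = list(grad_norms = model$grad_norms,
                                 losses = model$losses,
                                 n_steps = model$n_steps)),
                class = "trained_model")
    },
    predict = function(handle, images) {
      cpp_det_predict(handle$model, images)  # N x 2: [P(non-L3), P(L3)]
    })
  structure(tr, class = "trainer")
}

#' @rdname reference_detector
#' @export
reference_segmenter <- function(input_size = 32L, channels = 4L,
                                n_classes = 5L) {
  force(input_size); force(channels); force(n_classes)
  tr <- list(
    task = "segmentation",
    input_size = as.integer(input_size),
    n_classes = as.integer(n_classes),
    fit = function(images, masks, design, weights, seed = 1L) {
      w <- if (inherits(weights, "class_weights")) weights$weights else weights
      .check_design(design)
      model <- cpp_unet_fit(images, masks * 1.0, design, as.numeric(w),
                            as.integer(channels), as.integer(n_classes),
                            as.integer(seed))
      structure(list(backend = "reference_unet", model = model,
                     design = design,
                     meta = list(grad_norms = model$grad_norms,
                                 losses = model$losses,
                                 n_steps = model$n_steps)),
                class = "trained_model")
    },
    predict = function(handle, images) {
      # returns array S x S x K x N of per-pixel class probabilities
      K <- handle$model$n_classes
      raw <- cpp_unet_predict(handle$model, images)
      N <- dim(images)[3]
      S <- dim(raw)[1]
      out <- array(0, dim = c(S, S, K, N))
      for (n in seq_len(N))
        for (k in seq_len(K))
          out[, , k, n] <- raw[, , K * (n - 1) + k]
      out
    })
  structure(tr, class = "trainer")
}

.design_bounds <- list(
  l2_regularization = c(1e-4, 1e-2),
  initial_learning_rate = c(1e-4, 1e-2),
  batch_size = c(10, 32),
  gradient_threshold = c(1, 6),
  epochs = c(5, 20),
  momentum = c(0.7, 0.99)
)

.check_design <- function(design) {
  for (nm in names(.design_bounds)) {
    v <- design[[nm]]
    if (is.null(v)) stop(sprintf("design lacks '%s'", nm))
    b <- .design_bounds[[nm]]
    if (v < b[1] - 1e-9 || v > b[2] + 1e-9)
      stop(sprintf("design '%s' = %g outside [%g, %g]", nm, v, b[1], b[2]))
  }
  invisible(design)
}

#' Mid-range default design (no optimisation)
#'
#' Geometric midpoints for the log-scale variables, arithmetic midpoints
#' otherwise.
#'
#' @return a named list usable wherever a decoded design is expected.
#' @export
midrange_design <- function() {
  list(l2_regularization = 1e-3, initial_learning_rate = 1e-3,
       batch_size = 21L, gradient_threshold = 4L, epochs = 12L,
       momentum = 0.845)
}

#' Predict the L3 slice of one patient volume
#'
#' Preprocesses every slice, scores it with the detection model and returns
#' the index of the slice with the highest L3 probability (softmax output);
#' ties break toward the lowest index.
#'
#' @param trainer the detection `trainer` used to fit `handle`.
#' @param handle a trained model handle.
#' @param volume a `patient_volume`.
#' @param window,stretch preprocessing parameters (must match training).
#' @return list with `index` (predicted slice) and `p_l3` (per-slice
#'   probabilities).
#' @export
predict_l3_slice <- function(trainer, handle, volume,
                             window = c(-190, 150), stretch = c(1, 99)) {
  if (length(volume$slices) == 0) stop("empty volume")
  images <- .preprocess_stack(volume$slices, trainer$input_size,
                              window, stretch)
  probs <- trainer$predict(handle, images)
  p_l3 <- probs[, 2]
  list(index = which.max(p_l3), p_l3 = p_l3)
}
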