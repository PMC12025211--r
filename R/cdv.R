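#' Plan minority-class augmentation to a target ratio
#'
#' The augmentation-ratio correction design variable `d_a` expresses the
#' target minority count as a fraction of the majority count:
#' `target_minority = round(d_a * n_majority)`, with `d_a = 1` giving exact
#' 1:1 balance (the upper bound of the search range). The plan lists, for
#' each sample to synthesize, a source minority index (cycling through the
#' minority set), a transform drawn uniformly from rotation / horizontal
#' flip / vertical flip, and a per-transform seed. Deterministic given
#' `seed`. If the target does not exceed the existing minority count the
#' plan contains zero augmentations (originals are never deleted).
#'
#' @param n_minority,n_majority class counts in the training set.
#' @param d_a augmentation ratio in `(0, 1]`.
#' @param seed RNG seed for the transform draw.
#' @return an `augmentation_plan`: list with `n_minority`, `n_majority`,
#'   `target_minority`, `n_augmented_needed` and `op_sequence`
#'   (data frame with `source_index`, `transform`, `transform_seed`).
#' @export
make_augmentation_plan <- function(n_minority, n_majority, d_a, seed = 1L) {
  stop_if_not_scalar_number(d_a, "d_a")
  if (d_a <= 0 || d_a > 1) stop("'d_a' must lie in (0, 1]")
  if (n_minority < 1 || n_majority < 1) stop("class counts must be >= 1")
  target <- round(d_a * n_majority)
  need <- max(0L, as.integer(target - n_minority))
  ops <- with_seed(seed, data.frame(
    source_index = if (need > 0) ((seq_len(need) - 1L) %% n_minority) + 1L else integer(0),
    transform = if (need > 0)
      sample(c("rotation", "hflip", "vflip"), need, replace = TRUE) else character(0),
    transform_seed = if (need > 0)
      sample.int(.Machine$integer.max - 1L, need, replace = TRUE) else integer(0),
    stringsAsFactors = FALSE
  ))
  structure(list(n_minority = as.integer(n_minority),
                 n_majority = as.integer(n_majority),
                 d_a = d_a,
                 target_minority = as.integer(target),
                 n_augmented_needed = need,
                 op_sequence = ops,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Apply one augmentation transform to an image (and optionally its mask)
#'
#' Flips are exact index reversals (involutions). Rotation draws an angle
#' uniformly from `[-angle_range, angle_range]` degrees using
#' `transform_seed`, resamples the image bilinearly and the mask with
#' nearest-neighbour (label set preserved), and fills out-of-canvas pixels
#' with 0. Images stay in `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param transform one of `"rotation"`, `"hflip"`, `"vflip"`.
#' @param transform_seed seed for the rotation angle draw.
#' @param mask optional integer mask transformed in lockstep.
#' @param angle_range maximum absolute rotation angle in degrees.
#' @return the transformed image, or `list(image, mask)` when a mask is
#'   supplied.
#' @export
augment_image <- function(img, transform, transform_seed = 1L, mask = NULL,
                          angle_range = 15) {
  if (!transform %in% c("rotation", "hflip", "vflip"))
    stop(sprintf("unknown transform '%s'", transform))
  tf_img <- switch(transform,
    hflip = img[, rev(seq_len(ncol(img))), drop = FALSE],
    vflip = img[rev(seq_len(nrow(img))), , drop = FALSE],
    rotation = {
      ang <- with_seed(transform_seed, runif(1, -angle_range, angle_range))
      pmin(pmax(rotate_matrix(img, ang, "bilinear", fill = 0), 0), 1)
    })
  if (is.null(mask)) return(tf_img)
  tf_mask <- switch(transform,
    hflip = mask[, rev(seq_len(ncol(mask))), drop = FALSE],
    vflip = mask[rev(seq_len(nrow(mask))), , drop = FALSE],
    rotation = {
      ang <- with_seed(transform_seed, runif(1, -angle_range, angle_range))
      rotate_matrix(mask, ang, "nearest", fill = 0L)
    })
  list(image = tf_img, mask = tf_mask)
}

#' Augment a segmentation dataset to a fixed multiple of its size
#'
#' Originals are retained; `(factor - 1) * n` extra samples are generated
#' with [augment_image()], cycling through the originals, with image and
#' mask transformed together. Deterministic given `seed`.
#'
#' @param images list of image matrices.
#' @param masks list of matching mask matrices.
#' @param factor integer multiple of the original size (default 4).
#' @param seed RNG seed.
#' @param angle_range rotation range passed to [augment_image()].
#' @return `list(images, masks, is_augmented)`.
#' @export
segmentation_augment <- function(images, masks, factor = 4L, seed = 1L,
                                 angle_range = 15) {
  if (factor < 1) stop("'factor' must be >= 1")
  n <- length(images)
  stopifnot(length(masks) == n)
  need <- (as.integer(factor) - 1L) * n
  if (need == 0L)
    return(list(images = images, masks = masks,
                is_augmented = rep(FALSE, n)))
  ops <- with_seed(seed, data.frame(
    source_index = ((seq_len(need) - 1L) %% n) + 1L,
    transform = sample(c("rotation", "hflip", "vflip"), need, replace = TRUE),
    transform_seed = sample.int(.Machine$integer.max - 1L, need, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  extra <- lapply(seq_len(need), function(i) {
    augment_image(images[[ops$source_index[i]]], ops$transform[i],
                  ops$transform_seed[i], mask = masks[[ops$source_index[i]]],
                  angle_range = angle_range)
  })
  list(images = c(images, lapply(extra, `[[`, "image")),
       masks = c(masks, lapply(extra, `[[`, "mask")),
       is_augmented = c(rep(FALSE, n), rep(TRUE, need)))
}

#' Constrained class weights for cost-sensitive training
#'
#' The class-weight correction design variable `d_c` is bounded below by a
#' task-specific minimum: for slice detection the inverse square root of
#' each class frequency (`1/sqrt(f_k)`), and for segmentation the ratio of
#' the number of pixels in the class to the total pixel count (`f_k`, the
#' rule as printed in the source protocol; `min_rule = "inverse_pixel_ratio"`
#' switches to `1/f_k`). The applied weights are
#' `max(minimum_k, d_c_k)`, then rescaled to mean 1 so that weighted losses
#' are comparable across candidate weight vectors during optimisation. The
#' stored `minima` are pre-normalisation.
#'
#' @param class_frequencies positive per-class fractions summing to 1.
#' @param d_c per-class weight multipliers (default: the minima).
#' @param task `"detection"` or `"segmentation"`.
#' @param min_rule segmentation minimum rule (see above).
#' @return a `class_weights` object: list with `weights` (mean 1),
#'   `raw_weights`, `minima`, `task`.
#' @export
compute_class_weights <- function(class_frequencies, d_c = NULL,
                                  task = c("detection", "segmentation"),
                                  min_rule = c("pixel_ratio", "inverse_pixel_ratio")) {
  task <- match.arg(task)
  min_rule <- match.arg(min_rule)
  f <- class_frequencies
  if (any(f <= 0)) {
    k <- which(f <= 0)[1]
    nm <- if (!is.null(names(f))) names(f)[k] else as.character(k)
    stop(sprintf("class '%s' has zero (or negative) frequency", nm))
  }
  if (abs(sum(f) - 1) > 1e-9) stop("'class_frequencies' must sum to 1")
  minima <- if (task == "detection") 1 / sqrt(f)
            else if (min_rule == "pixel_ratio") f else 1 / f
  if (is.null(d_c)) d_c <- minima
  if (length(d_c) != length(f)) stop("'d_c' length must match class count")
  raw <- pmax(minima, d_c)
  structure(list(weights = raw / mean(raw),
                 raw_weights = raw,
                 minima = minima,
                 task = task,
                 min_rule = min_rule),
            class = "class_weights")
}

#' Weighted cross-entropy loss
#'
#' Mean over samples (or pixels) of `-w[y] * log(p[y])`, with probabilities
#' clamped at `1e-12`. With all weights equal to 1 this is the standard
#' cross-entropy.
#'
#' @param probs matrix of predicted class probabilities, one row per sample,
#'   columns ordered by class code (first column = code 0); rows must sum to
#'   1 (tolerance `1e-6`).
#' @param labels integer class codes (0-based) of the true classes.
#' @param weights per-class weights (numeric vector indexed by code + 1, or
#'   a [compute_class_weights()] object, whose normalised `weights` are used).
#' @return nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights) {
  if (inherits(weights, "class_weights")) weights <- weights$weights
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (nrow(probs) != length(labels)) stop("probs/labels shape mismatch")
  if (any(labels < 0) || any(labels >= ncol(probs)))
    stop("labels outside class-code range")
  if (length(weights) != ncol(probs))
    stop("weights length must equal number of classes")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  mean(-weights[labels + 1L] * log(pmax(p, 1e-12)))
}
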