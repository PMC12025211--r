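#' One-vs-rest confusion counts
#'
#' Computes per-class TP / FP / FN / TN over paired label vectors or masks,
#' one-vs-rest for each class code `0 .. n_classes - 1`. For every class,
#' `TP + FP + FN + TN` equals the total number of items.
#'
#' @param predicted,true integer vectors or matrices of class codes
#'   (same shape).
#' @param n_classes number of classes.
#' @return a `confusion_counts` object: integer matrix with one row per
#'   class (rownames = class codes) and columns `TP, FP, FN, TN`.
#' @export
confusion <- function(predicted, true, n_classes) {
  if (length(predicted) != length(true))
    stop("'predicted' and 'true' must have the same shape")
  p <- as.integer(predicted); t <- as.integer(true)
  lv <- 0:(n_classes - 1)
  if (any(!p %in% lv) || any(!t %in% lv))
    stop("labels outside class-code range")
  tab <- table(factor(p, levels = lv), factor(t, levels = lv))
  total <- length(p)
  tp <- diag(tab)
  fp <- rowSums(tab) - tp
  fn <- colSums(tab) - tp
  tn <- total - tp - fp - fn
  out <- cbind(TP = as.integer(tp), FP = as.integer(fp),
               FN = as.integer(fn), TN = as.integer(tn))
  rownames(out) <- lv
  structure(out, class = c("confusion_counts", class(out)))
}

.counts_mat <- function(counts) {
  m <- unclass(counts)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, names(m)))
  m
}

#' Overlap and rate metrics from confusion counts
#'
#' `jaccard = TP / (TP + FP + FN)`, `dice = 2 TP / (2 TP + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#' A class absent from both prediction and truth (`TP = FP = FN = 0`)
#' scores 1 by convention. The identity `dice = 2 J / (1 + J)` holds
#' everywhere.
#'
#' @param counts a [confusion()] object (or a matrix with columns
#'   `TP, FP, FN, TN`).
#' @return named numeric vector, one score per class.
#' @export
jaccard <- function(counts) {
  m <- .counts_mat(counts)
  den <- m[, "TP"] + m[, "FP"] + m[, "FN"]
  ifelse(den == 0, 1, m[, "TP"] / pmax(den, 1))
}

#' @rdname jaccard
#' @export
dice <- function(counts) {
  m <- .counts_mat(counts)
  den <- 2 * m[, "TP"] + m[, "FP"] + m[, "FN"]
  ifelse(den == 0, 1, 2 * m[, "TP"] / pmax(den, 1))
}

#' @rdname jaccard
#' @export
sensitivity <- function(counts) {
  m <- .counts_mat(counts)
  den <- m[, "TP"] + m[, "FN"]
  ifelse(den == 0, 1, m[, "TP"] / pmax(den, 1))
}

#' @rdname jaccard
#' @export
specificity <- function(counts) {
  m <- .counts_mat(counts)
  den <- m[, "TN"] + m[, "FP"]
  ifelse(den == 0, 1, m[, "TN"] / pmax(den, 1))
}

# four-connected boundary: mask pixels with at least one four-neighbour
# outside the mask (the image border counts as outside)
boundary_pixels <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  inside <- mask
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- inside
  core <- pad[2:(n + 1), 2:(m + 1)]
  nb <- pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
        pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  which(core & !nb, arr.ind = TRUE)
}

#' Mean surface distance between two masks
#'
#' The boundary of a mask is the set of its pixels with at least one
#' four-connected neighbour outside it. In `"directed"` mode the metric is
#' the mean, over predicted-boundary pixels, of the Euclidean distance to
#' the nearest true-boundary pixel; `"symmetric"` averages the two directed
#' distances. Distances are scaled by `pixel_spacing_mm` (pass the spacing
#' at the masks' current resolution, i.e. native spacing times resize
#' factor). If either boundary is empty the metric is undefined and `NA` is
#' returned.
#'
#' @param pred_mask,true_mask masks of class codes (same shape).
#' @param class class code whose surface is compared (default 1).
#' @param pixel_spacing_mm physical pixel size at this resolution.
#' @param mode `"directed"` (predicted to truth) or `"symmetric"`.
#' @return distance in mm, or `NA_real_` if undefined.
#' @export
mean_surface_distance <- function(pred_mask, true_mask, class = 1L,
                                  pixel_spacing_mm = 1,
                                  mode = c("directed", "symmetric")) {
  mode <- match.arg(mode)
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("masks must have the same shape")
  a <- boundary_pixels(pred_mask == class)
  b <- boundary_pixels(true_mask == class)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  directed <- function(p, q) {
    d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2
    mean(sqrt(do.call(pmin, as.data.frame(d2))))
  }
  d <- if (mode == "directed") directed(a, b)
       else (directed(a, b) + directed(b, a)) / 2
  d * pixel_spacing_mm
}

#' Slice-position error of L3 detection
#'
#' Signed difference `predicted - true` between slice indices;
#' `abs_slice_error` is its absolute value.
#'
#' @param predicted,true slice indices.
#' @return signed (or nonnegative) difference.
#' @export
slice_error <- function(predicted, true) predicted - true

#' @rdname slice_error
#' @export
abs_slice_error <- function(predicted, true) abs(predicted - true)

#' Bland-Altman agreement summary
#'
#' Differences are `predicted - true`; the 95\% limits of agreement are
#' `mean +/- 1.96 * SD` with the sample (n-1) standard deviation. The
#' within-limits fraction uses strict inequalities, so when all differences
#' are equal the limits collapse onto the mean and the fraction is 0
#' (degenerate case).
#'
#' @param predicted,true paired measurements (>= 2 pairs).
#' @return a `bland_altman` object: list with `mean_difference`,
#'   `sd_difference`, `lower_limit`, `upper_limit`, `fraction_within`, `n`.
#' @export
bland_altman <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("pairs must have equal length")
  if (length(predicted) < 2) stop("at least 2 pairs are required")
  d <- predicted - true
  m <- mean(d); s <- sd(d)
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  structure(list(mean_difference = m,
                 sd_difference = s,
                 lower_limit = lo,
                 upper_limit = hi,
                 fraction_within = mean(d > lo & d < hi),
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean %.3f, LoA [%.3f, %.3f], %.1f%% within (n=%d)\n",
              x$mean_difference, x$lower_limit, x$upper_limit,
              100 * x$fraction_within, x$n))
  invisible(x)
}

#' Physical tissue area from a (possibly resized) mask
#'
#' `area = pixel count * spacing^2 * (native_size / current_size)^2`; the
#' squared ratio corrects for resizing (factor 4 exactly for a 512 to 256
#' resize).
#'
#' @param mask mask of class codes at its current resolution.
#' @param class class code to measure.
#' @param pixel_spacing_mm physical pixel size at the native resolution.
#' @param native_size original side length; default: the mask's own side
#'   (factor 1).
#' @return area in mm^2.
#' @export
tissue_area <- function(mask, class, pixel_spacing_mm,
                        native_size = nrow(mask)) {
  if (pixel_spacing_mm <= 0) stop("'pixel_spacing_mm' must be positive")
  sum(mask == class) * pixel_spacing_mm^2 * (native_size / nrow(mask))^2
}

#' Coefficient of determination between predicted and reference values
#'
#' Ordinary least-squares regression R^2 (offset- and scale-invariant;
#' equal to the squared Pearson correlation). Errors on fewer than 2 pairs
#' or zero reference variance; returns 0 for constant predictions.
#'
#' @param predicted,reference paired numeric vectors.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("pairs must have equal length")
  if (length(predicted) < 2) stop("at least 2 pairs are required")
  if (var(reference) == 0) stop("reference values have zero variance")
  r2 <- suppressWarnings(cor(predicted, reference)^2)
  if (is.na(r2)) 0 else r2
}

#' Per-class segmentation metric battery
#'
#' Jaccard, Dice, sensitivity, specificity and mean surface distance for
#' each requested class, plus macro averages over those classes (MSD macro
#' average skips undefined entries).
#'
#' @param pred_mask,true_mask masks of class codes.
#' @param pixel_spacing_mm spacing at the masks' current resolution.
#' @param classes class codes to evaluate (default foreground `1:4`).
#' @param n_classes total number of classes (codes `0:(n_classes-1)`).
#' @param msd_mode passed to [mean_surface_distance()].
#' @return list with `per_class` (data frame) and `macro` (named vector).
#' @export
seg_metrics <- function(pred_mask, true_mask, pixel_spacing_mm = 1,
                        classes = 1:4, n_classes = 5,
                        msd_mode = "directed") {
  cc <- confusion(pred_mask, true_mask, n_classes)
  sel <- as.character(classes)
  per <- data.frame(
    class = classes,
    jaccard = jaccard(cc)[sel],
    dice = dice(cc)[sel],
    sensitivity = sensitivity(cc)[sel],
    specificity = specificity(cc)[sel],
    msd = vapply(classes, function(k)
      mean_surface_distance(pred_mask, true_mask, k, pixel_spacing_mm,
                            msd_mode), 0),
    row.names = NULL
  )
  macro <- c(jaccard = mean(per$jaccard), dice = mean(per$dice),
             sensitivity = mean(per$sensitivity),
             specificity = mean(per$specificity),
             msd = mean(per$msd, na.rm = TRUE))
  list(per_class = per, macro = macro)
}
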