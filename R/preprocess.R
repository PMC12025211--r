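#' Clip Hounsfield units to a display window
#'
#' CT windowing: every value below `lo` saturates to `lo` and every value
#' above `hi` saturates to `hi`. The default window `[-190, 150]` spans the
#' muscle/fat/bone range used for L3 detection and tissue segmentation.
#' Idempotent.
#'
#' @param hu numeric matrix of Hounsfield units (must be finite).
#' @param lo,hi window bounds, `lo < hi`.
#' @return a matrix of the same shape with values in `[lo, hi]`.
#' @export
apply_hu_window <- function(hu, lo = -190, hi = 150) {
  if (!is.numeric(hu)) stop("'hu' must be numeric")
  if (any(!is.finite(hu))) stop("'hu' contains non-finite values")
  if (!(lo < hi)) stop("'lo' must be < 'hi'")
  out <- pmin(pmax(hu, lo), hi)
  dim(out) <- dim(hu)
  out
}

#' Histogram stretching to the unit interval
#'
#' Linearly maps the `p_lo` percentile of the input to 0 and the `p_hi`
#' percentile to 1, clipping the result to `[0, 1]`. A constant (degenerate)
#' image maps to all zeros.
#'
#' @param hu numeric matrix (typically windowed HU values).
#' @param p_lo,p_hi percentile endpoints in `[0, 100]`, `p_lo < p_hi`.
#' @return a matrix with all values in `[0, 1]`.
#' @export
histogram_stretch <- function(hu, p_lo = 1, p_hi = 99) {
  if (!(p_lo < p_hi)) stop("'p_lo' must be < 'p_hi'")
  q <- quantile(hu, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
  if (!is.finite(q[1]) || q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2])))
    return(matrix(0, nrow(hu), ncol(hu)))
  out <- (hu - q[1]) / (q[2] - q[1])
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(hu)
  out
}

# separable grid resampling -----------------------------------------------

# source coordinate (0-based) of each target pixel centre; exact identity
# when target == n
.src_coords <- function(n, target) {
  (seq_len(target) - 0.5) * n / target - 0.5
}

resample_bilinear <- function(mat, target) {
  n <- nrow(mat)
  if (target == n) return(mat)
  src <- .src_coords(n, target)
  i0 <- pmin(pmax(floor(src), 0), n - 1)
  f <- pmin(pmax(src - i0, 0), 1)
  i1 <- pmin(i0 + 1, n - 1)
  r0 <- i0 + 1; r1 <- i1 + 1
  # rows then columns (separable)
  a <- mat[r0, , drop = FALSE] * (1 - f) + mat[r1, , drop = FALSE] * f
  a[, r0, drop = FALSE] %*% diag(1 - f, target) +
    a[, r1, drop = FALSE] %*% diag(f, target)
}

resample_nearest <- function(mat, target) {
  n <- nrow(mat)
  if (target == n) return(mat)
  src <- .src_coords(n, target)
  idx <- pmin(pmax(floor(src + 0.5), 0), n - 1) + 1
  mat[idx, idx, drop = FALSE]
}

#' Resize a normalized image (bilinear) or a label mask (nearest-neighbour)
#'
#' Images are resampled bilinearly; masks use nearest-neighbour so that the
#' label set is preserved exactly. Only square inputs and downsizing (or
#' identity) are supported; `target == nrow(x)` is an exact identity. The
#' physical pixel spacing refers to the native resolution; the resize factor
#' is recoverable as `native_size / target`, and tissue areas measured on a
#' resized mask must be multiplied by its square (factor 4 for 512 to 256).
#'
#' @param img,mask square numeric matrix (image in `[0, 1]`; mask of
#'   integer class codes).
#' @param target target side length, `<= nrow(x)`.
#' @return the resized matrix.
#' @export
resize_image <- function(img, target = 256) {
  if (nrow(img) != ncol(img)) stop("image must be square")
  if (target > nrow(img))
    stop(sprintf("target size %d exceeds native size %d", target, nrow(img)))
  if (target < 1) stop("'target' must be positive")
  resample_bilinear(img, as.integer(target))
}

#' @rdname resize_image
#' @export
resize_mask <- function(mask, target = 256) {
  if (nrow(mask) != ncol(mask)) stop("mask must be square")
  if (target > nrow(mask))
    stop(sprintf("target size %d exceeds native size %d", target, nrow(mask)))
  if (target < 1) stop("'target' must be positive")
  out <- resample_nearest(mask, as.integer(target))
  storage.mode(out) <- storage.mode(mask)
  out
}

#' Full preprocessing of one raw CT slice
#'
#' Applies the standard chain: HU window, histogram stretch to `[0, 1]`,
#' optional resize to the network input size. Deterministic.
#'
#' @param hu square matrix of raw HU values.
#' @param pixel_spacing_mm physical pixel size at the native resolution.
#' @param target_size optional side length after resize (default: native).
#' @param window HU window `c(lo, hi)`.
#' @param stretch percentile endpoints `c(p_lo, p_hi)` for the stretch.
#' @return a `norm_image` object: list with `intensity` (matrix in
#'   `[0, 1]`), `native_size`, `current_size`, `pixel_spacing_mm`.
#' @export
preprocess_slice <- function(hu, pixel_spacing_mm = 1,
                             target_size = NULL,
                             window = c(-190, 150),
                             stretch = c(1, 99)) {
  native <- nrow(hu)
  x <- apply_hu_window(hu, window[1], window[2])
  x <- histogram_stretch(x, stretch[1], stretch[2])
  if (!is.null(target_size)) x <- resize_image(x, target_size)
  structure(list(intensity = x,
                 native_size = native,
                 current_size = nrow(x),
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "norm_image")
}

# rotation about the image centre, inverse-mapped grid sampling,
# out-of-canvas filled with `fill`
rotate_matrix <- function(mat, angle_deg, interp = c("bilinear", "nearest"),
                          fill = 0) {
  interp <- match.arg(interp)
  n <- nrow(mat); m <- ncol(mat)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- (m + 1) / 2; cy <- (n + 1) / 2
  xs <- matrix(rep(seq_len(m), each = n), n, m) - cx
  ys <- matrix(rep(seq_len(n), times = m), n, m) - cy
  sx <- ct * xs + st * ys + cx   # inverse rotation
  sy <- -st * xs + ct * ys + cy
  out <- matrix(fill, n, m)
  if (interp == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    out[ok] <- mat[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    ok <- r0 >= 1 & r0 + 1 <= n & c0 >= 1 & c0 + 1 <= m
    g <- function(ri, ci) mat[cbind(ri[ok], ci[ok])]
    out[ok] <- g(r0, c0) * (1 - fr[ok]) * (1 - fc[ok]) +
      g(r0 + 1, c0) * fr[ok] * (1 - fc[ok]) +
      g(r0, c0 + 1) * (1 - fr[ok]) * fc[ok] +
      g(r0 + 1, c0 + 1) * fr[ok] * fc[ok]
  }
  storage.mode(out) <- storage.mode(mat)
  out
}
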