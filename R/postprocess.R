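#' Hounsfield-unit range table for mask refinement
#'
#' Default intervals: SM `[29, 150]`, SAT `[-150, -50]`, VAT `[-190, -30]`,
#' keyed by class codes 1-3.
#'
#' @param sm,sat,vat inclusive HU intervals `c(lo, hi)`.
#' @return an `hu_range_table`: named list of intervals keyed `"1"`, `"2"`,
#'   `"3"`.
#' @export
hu_range_table <- function(sm = c(29, 150), sat = c(-150, -50),
                           vat = c(-190, -30)) {
  tab <- list(`1` = sm, `2` = sat, `3` = vat)
  for (k in names(tab)) {
    iv <- tab[[k]]
    if (length(iv) != 2 || !(iv[1] <= iv[2]))
      stop(sprintf("interval for class %s must be nonempty c(lo, hi)", k))
  }
  structure(tab, class = "hu_range_table")
}

#' Refine a predicted segmentation mask by HU range
#'
#' Pixels predicted as SM, SAT or VAT whose original (un-windowed) HU value
#' lies outside the class's interval are vetoed. The default rule sends
#' them to "other" (code 4) rather than to another tissue, because the SAT
#' interval is contained in the VAT interval, making range-based
#' reassignment between the fat classes ambiguous: the spatial prediction
#' is trusted for the class choice and HU only vetoes.
#' `out_of_range = "nearest_valid"` instead assigns the tissue class whose
#' interval contains the HU value (nearest interval centre on ties; code 4
#' if no interval matches). Background (0) and other (4) pixels are never
#' touched; the operation is idempotent and never alters image data.
#'
#' @param predicted_mask mask of class codes 0-4.
#' @param hu matrix of original HU values; if its resolution differs from
#'   the mask it is resampled to the mask's grid with nearest-neighbour.
#' @param table an [hu_range_table()].
#' @param out_of_range `"other"` (default) or `"nearest_valid"`.
#' @return the refined mask.
#' @export
hu_refine <- function(predicted_mask, hu, table = hu_range_table(),
                      out_of_range = c("other", "nearest_valid")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(inherits(table, "hu_range_table"))
  if (!all(dim(hu) == dim(predicted_mask))) {
    if (nrow(hu) != ncol(hu) || nrow(predicted_mask) != ncol(predicted_mask))
      stop("mask and HU array shapes are incompatible")
    if (nrow(hu) < nrow(predicted_mask))
      stop("HU array must be at least as large as the mask")
    hu <- resample_nearest(hu, nrow(predicted_mask))
  }
  out <- predicted_mask
  for (k in 1:3) {
    iv <- table[[as.character(k)]]
    bad <- predicted_mask == k & (hu < iv[1] | hu > iv[2])
    if (!any(bad)) next
    if (out_of_range == "other") {
      out[bad] <- 4L
    } else {
      centres <- vapply(table, mean, 0)
      idx <- which(bad)
      for (i in idx) {
        v <- hu[i]
        valid <- which(vapply(1:3, function(j) {
          jv <- table[[as.character(j)]]
          v >= jv[1] && v <= jv[2]
        }, TRUE))
        out[i] <- if (length(valid) == 0) 4L
                  else valid[which.min(abs(centres[valid] - v))]
      }
    }
  }
  storage.mode(out) <- storage.mode(predicted_mask)
  out
}
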