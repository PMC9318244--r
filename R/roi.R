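#' Tile non-overlapping square ROIs inside a lesion
#'
#' Deterministic greedy raster placement: candidate top-left corners are
#' scanned row by row, left to right, at stride 1; a candidate is accepted
#' iff its `roiSize` square lies entirely inside the mask and overlaps no
#' previously accepted ROI. Larger lesions therefore yield more ROIs, and
#' together the ROIs cover the lesion without overlap or background
#' contamination. The fully-inside test uses a summed-area table of the
#' mask, so the scan is linear in the image size.
#'
#' An optional `placement = "centroid"` variant orders candidates by
#' distance from the mask centroid (ties broken in raster order) instead
#' of pure raster order.
#'
#' @param img a [GrayImage-class] (the grayscale photograph the surface
#'   texture is read from).
#' @param mask the [LesionMask-class]; same dimensions as `img`.
#' @param roiSize ROI side in pixels (the study default is 450).
#' @param placement `"raster"` (default) or `"centroid"`.
#' @return an [ROISet-class]; when no ROI fits, an empty set with
#'   `tooSmall = TRUE` and a message (the lesion is excluded from surface
#'   analysis, not an error).
#' @export
extractROIs <- function(img, mask, roiSize = 450L,
                        placement = c("raster", "centroid")) {
  placement <- match.arg(placement)
  roiSize <- as.integer(roiSize)
  if (roiSize < 8L) stop("roiSize must be >= 8")
  m <- pixels(mask)
  if (!identical(dim(m), dim(pixels(img))))
    stop("image and mask dimensions differ")
  nr <- nrow(m); nc <- ncol(m)
  empty <- function() {
    message("lesion too small for surface analysis at roiSize = ", roiSize)
    new("ROISet", roiSize = roiSize,
        origins = matrix(integer(), 0L, 2L,
                         dimnames = list(NULL, c("row", "col"))),
        patches = list(), tooSmall = TRUE)
  }
  if (nr < roiSize || nc < roiSize) return(empty())
  # summed-area table with a zero top/left border
  sat <- rbind(0, cbind(0, apply(apply(m, 2L, cumsum), 1L, cumsum)))
  sat <- t(sat)  # restore orientation after the double apply
  boxSum <- function(r, c)  # elementwise sum over m[r:(r+s-1), c:(c+s-1)]
    sat[cbind(r + roiSize, c + roiSize)] - sat[cbind(r, c + roiSize)] -
      sat[cbind(r + roiSize, c)] + sat[cbind(r, c)]
  rs <- seq_len(nr - roiSize + 1L)
  cs <- seq_len(nc - roiSize + 1L)
  full <- outer(rs, cs, boxSum) == roiSize^2
  cand <- which(full, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty())
  # raster order: by row then column
  ord <- order(cand[, 1L], cand[, 2L])
  if (placement == "centroid") {
    ctr <- c(mean(which(m, arr.ind = TRUE)[, 1L]),
             mean(which(m, arr.ind = TRUE)[, 2L]))
    d2 <- (cand[, 1L] + (roiSize - 1) / 2 - ctr[1])^2 +
          (cand[, 2L] + (roiSize - 1) / 2 - ctr[2])^2
    ord <- order(d2, cand[, 1L], cand[, 2L])
  }
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(integer(), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; c <- cand[i, 2L]
    if (nrow(acc) == 0L ||
        !any(abs(acc[, 1L] - r) < roiSize & abs(acc[, 2L] - c) < roiSize))
      acc <- rbind(acc, c(r, c))
  }
  dimnames(acc) <- list(NULL, c("row", "col"))
  px <- pixels(img)
  pat <- lapply(seq_len(nrow(acc)), function(i)
    GrayImage(px[acc[i, 1L]:(acc[i, 1L] + roiSize - 1L),
                 acc[i, 2L]:(acc[i, 2L] + roiSize - 1L)],
              mmPerPixel(img)))
  new("ROISet", roiSize = roiSize, origins = acc, patches = pat,
      tooSmall = FALSE)
}

#' @rdname ROISet-accessors
#' @param object an [ROISet-class].
#' @export
setMethod("origins", "ROISet", function(object) object@origins)

#' @rdname ROISet-accessors
#' @export
setMethod("patches", "ROISet", function(object) object@patches)

#' @rdname ROISet-accessors
#' @export
setMethod("roiSize", "ROISet", function(object) object@roiSize)

#' @rdname ROISet-accessors
#' @export
setMethod("length", "ROISet", function(x) length(x@patches))

setMethod("show", "ROISet", function(object) {
  if (object@tooSmall)
    cat(sprintf("ROISet: lesion too small for %dpx ROIs\n", object@roiSize))
  else
    cat(sprintf("ROISet: %d non-overlapping %dx%d ROIs\n",
                length(object@patches), object@roiSize, object@roiSize))
})
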