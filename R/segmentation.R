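#' Convert an RGB image to 8-bit grayscale
#'
#' Rec. 709 luma weights (0.2126, 0.7152, 0.0722), rounded half-up to the
#' nearest integer level.
#'
#' @param rgb numeric array height x width x 3 of 8-bit values (0-255).
#' @param mmPerPixel optional calibration attached to the result.
#' @return a [GrayImage-class].
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' pixels(toGrayscale(px))  # 54
#' @export
toGrayscale <- function(rgb, mmPerPixel = NA_real_) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("expected a height x width x 3 array")
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255) || any(rgb != trunc(rgb)))
    stop("expected 8-bit channel values (integers in [0, 255])")
  w <- c(0.2126, 0.7152, 0.0722)
  y <- w[1] * rgb[, , 1] + w[2] * rgb[, , 2] + w[3] * rgb[, , 3]
  GrayImage(matrix(floor(y + 0.5), dim(rgb)[1], dim(rgb)[2]), mmPerPixel)
}

#' Invert grayscale tones
#'
#' Each pixel v becomes 255 - v; an involution.
#'
#' @param img a [GrayImage-class].
#' @return the inverted [GrayImage-class] (calibration preserved).
#' @export
invertImage <- function(img) {
  GrayImage(255 - pixels(img), mmPerPixel(img))
}

#' Divide-blend two grayscale layers
#'
#' Raster-editor "divide" blend used to separate a dark lesion from a
#' bright skin background: per pixel, E = lower * 256 / (upper + 1),
#' truncated toward zero and clamped to \[0, 255\] (the +1 guards against
#' division by zero). With `upper = invertImage(lower)` this is
#' E = 256 I / (256 - I), strictly increasing in the input intensity I, so
#' bright background saturates to white while the dark lesion keeps its
#' detail.
#'
#' @param lower,upper [GrayImage-class] layers of identical dimensions.
#' @return the blended [GrayImage-class] (calibration taken from `lower`).
#' @export
divideBlend <- function(lower, upper) {
  lo <- pixels(lower); up <- pixels(upper)
  if (!identical(dim(lo), dim(up)))
    stop("lower and upper layers must have identical dimensions")
  e <- trunc(lo * 256 / (up + 1))
  GrayImage(pmin(e, 255), mmPerPixel(lower))
}

#' Extract a clean binary lesion mask from a divide-blended image
#'
#' Pixels strictly below `whiteThreshold` are lesion candidates. Connected
#' components other than the largest are removed (a deterministic
#' replacement for manual background-artifact erasing) and fully enclosed
#' holes are filled, yielding a single-component mask. A warning is issued
#' if a discarded component exceeds `minComponentFraction` of the largest,
#' since that may indicate genuine structure rather than an artifact.
#'
#' @param blended a [GrayImage-class], typically from [divideBlend()].
#' @param whiteThreshold intensities below this count as lesion (default 250).
#' @param minComponentFraction components at least this fraction of the
#'   largest trigger a warning when discarded (default 0.01).
#' @return a [LesionMask-class].
#' @export
extractMask <- function(blended, whiteThreshold = 250, minComponentFraction = 0.01) {
  cand <- pixels(blended) < whiteThreshold
  if (!any(cand)) stop("no lesion found: no pixel below the white threshold")
  lab <- EBImage::bwlabel(cand)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  big <- which(sizes >= minComponentFraction * sizes[keep])
  if (length(big) > 1L)
    warning(length(big) - 1L, " non-largest component(s) above ",
            "minComponentFraction were discarded")
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  LesionMask(matrix(as.logical(mask), nrow(cand), ncol(cand)))
}

#' Segment a lesion photograph end to end
#'
#' Convenience chain: grayscale conversion (if RGB), tone inversion,
#' divide blend of the grayscale layer over its inversion, and mask
#' extraction.
#'
#' @param img a [GrayImage-class] or an RGB array (height x width x 3,
#'   8-bit).
#' @param whiteThreshold,minComponentFraction passed to [extractMask()].
#' @param mmPerPixel calibration used when `img` is a raw array.
#' @return list with elements `gray`, `blended` ([GrayImage-class]) and
#'   `mask` ([LesionMask-class]).
#' @export
segmentLesion <- function(img, whiteThreshold = 250, minComponentFraction = 0.01,
                          mmPerPixel = NA_real_) {
  if (!is(img, "GrayImage")) {
    img <- if (length(dim(img)) == 3L) toGrayscale(img, mmPerPixel)
           else GrayImage(img, mmPerPixel)
  }
  blended <- divideBlend(img, invertImage(img))
  list(gray = img, blended = blended,
       mask = extractMask(blended, whiteThreshold, minComponentFraction))
}
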