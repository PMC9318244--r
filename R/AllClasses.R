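#' @import methods
NULL

#' GrayImage: an 8-bit grayscale image with optional physical calibration
#'
#' The unit all processing operates on: a numeric matrix of integer-valued
#' intensities in \[0, 255\], rows indexing image rows (y, top to bottom) and
#' columns indexing image columns (x, left to right), plus an optional
#' millimetre-per-pixel calibration carried through to morphometry.
#'
#' @slot pixels numeric matrix of integer-valued intensities in \[0, 255\].
#' @slot mmPerPixel single numeric, millimetres per pixel; `NA_real_` when
#'   the image is uncalibrated.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", mmPerPixel = "numeric"),
  prototype(pixels = matrix(0, 1, 1), mmPerPixel = NA_real_))

setValidity("GrayImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L) return("image must be at least 1x1")
  if (anyNA(px)) return("pixels must not contain NA")
  if (any(px < 0 | px > 255)) return("intensities must lie in [0, 255]")
  if (any(px != trunc(px))) return("intensities must be integer-valued")
  if (length(object@mmPerPixel) != 1L)
    return("mmPerPixel must be a single value (NA when uncalibrated)")
  if (!is.na(object@mmPerPixel) && object@mmPerPixel <= 0)
    return("mmPerPixel must be positive")
  TRUE
})

#' LesionMask: binary lesion segmentation mask
#'
#' Logical matrix with the same dimensions as its source image; `TRUE`
#' marks lesion pixels. After segmentation cleanup the foreground is a
#' single connected component with holes filled.
#'
#' @slot pixels logical matrix; `TRUE` = lesion.
#' @export
setClass("LesionMask", representation(pixels = "matrix"))

setValidity("LesionMask", function(object) {
  px <- object@pixels
  if (!is.logical(px)) return("mask pixels must be logical")
  if (anyNA(px)) return("mask must not contain NA")
  if (!any(px)) return("mask foreground is empty")
  TRUE
})

#' ScaleSeries: the ordered box sizes of a box-counting run
#'
#' @slot scheme one of `"power"`, `"block"`, `"explicit"`.
#' @slot scales integer vector of box sizes (pixels), ascending, distinct,
#'   each >= 2. Validity against a particular image (scale <= half the
#'   smaller image dimension) is checked by [estimateFD()].
#' @export
setClass("ScaleSeries", representation(scheme = "character", scales = "integer"))

setValidity("ScaleSeries", function(object) {
  if (!object@scheme %in% c("power", "block", "explicit"))
    return("scheme must be 'power', 'block' or 'explicit'")
  s <- object@scales
  if (length(s) < 3L) return("at least 3 scales are required")
  if (anyDuplicated(s)) return("scales must be distinct")
  if (is.unsorted(s)) return("scales must be ascending")
  if (any(s < 2L)) return("every scale must be >= 2 pixels")
  TRUE
})

#' FDResult: an intensity-difference box-counting fractal dimension estimate
#'
#' @slot fd least-squares slope of ln I(eps) versus ln(1/eps).
#' @slot intercept regression intercept.
#' @slot rSquared goodness of fit in \[0, 1\].
#' @slot perScale data.frame with columns `eps` and `I` (per-scale sums).
#' @slot metadata list: scale scheme, whether any scale produced partial
#'   edge boxes, grid-offset setting.
#' @export
setClass("FDResult",
  representation(fd = "numeric", intercept = "numeric", rSquared = "numeric",
                 perScale = "data.frame", metadata = "list"))

setValidity("FDResult", function(object) {
  ps <- object@perScale
  if (!all(c("eps", "I") %in% names(ps))) return("perScale needs eps and I columns")
  if (any(ps$I < 1)) return("each box contributes at least 1, so I(eps) >= box count >= 1")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' MorphometryResult: area and perimeter of a lesion mask
#'
#' @slot area lesion area (mm^2, or pixels^2 when uncalibrated).
#' @slot perimeter boundary length (mm, or pixels when uncalibrated).
#' @slot pixelArea foreground pixel count.
#' @slot pixelPerimeter boundary polygon length in pixel units.
#' @slot units `"mm"` or `"px"`.
#' @slot method character description of the perimeter estimator.
#' @export
setClass("MorphometryResult",
  representation(area = "numeric", perimeter = "numeric",
                 pixelArea = "numeric", pixelPerimeter = "numeric",
                 units = "character", method = "character"))

#' ROISet: non-overlapping square regions of interest inside a lesion
#'
#' @slot roiSize side of each square ROI in pixels.
#' @slot origins integer matrix (n x 2, columns `row`, `col`) of top-left
#'   corners in source-image coordinates; zero rows when no ROI fits.
#' @slot patches list of [GrayImage-class] patches, `roiSize` square each.
#' @slot tooSmall `TRUE` when no ROI could be placed (lesion excluded from
#'   surface analysis).
#' @export
setClass("ROISet",
  representation(roiSize = "integer", origins = "matrix",
                 patches = "list", tooSmall = "logical"))

setValidity("ROISet", function(object) {
  og <- object@origins
  if (ncol(og) != 2L) return("origins must have two columns (row, col)")
  if (nrow(og) != length(object@patches))
    return("origins and patches must agree in length")
  if (nrow(og) >= 2L) {
    s <- object@roiSize
    for (i in seq_len(nrow(og) - 1L)) {
      dr <- abs(og[(i + 1L):nrow(og), 1L] - og[i, 1L])
      dc <- abs(og[(i + 1L):nrow(og), 2L] - og[i, 2L])
      if (any(dr < s & dc < s)) return("ROIs must not overlap")
    }
  }
  if (object@tooSmall && nrow(og) > 0L)
    return("a set flagged too-small must be empty")
  TRUE
})

#' SyntheticLesionParams: controls of the simulated lesion renderer
#'
#' Parameters of one simulated lesion photograph: a dark, roughly
#' elliptical lesion with a radial-Fourier irregular border and fractional
#' Brownian pigment texture on a lighter skin background, rendered either
#' under polarized (PL) or non-polarized (NPL) illumination. The NPL
#' variant compresses lesion/background contrast and adds specular
#' speckle; boundary and texture are seeded independently of illumination
#' so that the PL/NPL pair shares them exactly.
#'
#' @slot imageWidth,imageHeight image dimensions in pixels.
#' @slot baseRadius mean lesion radius in pixels.
#' @slot irregularityAmplitude dimensionless >= 0; scales the radial
#'   boundary perturbation.
#' @slot harmonics number of radial Fourier modes (k = 2 .. harmonics + 1).
#' @slot textureHurst Hurst exponent of the pigment texture in (0, 1);
#'   lower = rougher.
#' @slot textureSd texture contrast in grey levels (0 = flat lesion).
#' @slot lesionMean,backgroundMean mean 8-bit intensities; the background
#'   must be brighter than the lesion.
#' @slot illumination `"PL"` or `"NPL"`.
#' @slot nplContrastFactor contrast retained under NPL, in (0, 1].
#' @slot specularNoiseDensity fraction of pixels hit by specular speckle
#'   under NPL.
#' @slot seed integer master seed; all randomness flows from it through
#'   fixed substreams.
#' @export
setClass("SyntheticLesionParams",
  representation(imageWidth = "integer", imageHeight = "integer",
                 baseRadius = "numeric", irregularityAmplitude = "numeric",
                 harmonics = "integer", textureHurst = "numeric",
                 textureSd = "numeric", lesionMean = "numeric",
                 backgroundMean = "numeric", illumination = "character",
                 nplContrastFactor = "numeric",
                 specularNoiseDensity = "numeric", seed = "integer"))

setValidity("SyntheticLesionParams", function(object) {
  if (object@imageWidth < 16L || object@imageHeight < 16L)
    return("image must be at least 16x16")
  if (object@baseRadius <= 0) return("baseRadius must be positive")
  if (object@irregularityAmplitude < 0)
    return("irregularityAmplitude must be >= 0")
  if (object@harmonics < 1L) return("at least one harmonic is required")
  if (object@textureHurst <= 0 || object@textureHurst >= 1)
    return("textureHurst must lie in (0, 1)")
  if (object@textureSd < 0) return("textureSd must be >= 0")
  if (object@backgroundMean <= object@lesionMean)
    return("lesion must be darker than the background")
  if (any(c(object@lesionMean, object@backgroundMean) < 0) ||
      any(c(object@lesionMean, object@backgroundMean) > 255))
    return("mean intensities must lie in [0, 255]")
  if (!object@illumination %in% c("PL", "NPL"))
    return("illumination must be 'PL' or 'NPL'")
  if (object@nplContrastFactor <= 0 || object@nplContrastFactor > 1)
    return("nplContrastFactor must lie in (0, 1]")
  if (object@specularNoiseDensity < 0 || object@specularNoiseDensity > 1)
    return("specularNoiseDensity must lie in [0, 1]")
  TRUE
})

#' StatsReport: one assembled comparison table
#'
#' @slot test name of the statistical test actually applied.
#' @slot decision `"parametric"` or `"nonparametric"` (normality gate).
#' @slot summary data.frame of group-level descriptives (means, SDs, n,
#'   mean ranks where applicable).
#' @slot pairwise named list of pairwise p-value matrices (symmetric,
#'   `NA` diagonal), or an empty list for two-sample reports.
#' @slot pValues named numeric vector of omnibus / two-sample p-values.
#' @slot notes character vector of logged exclusions and caveats.
#' @export
setClass("StatsReport",
  representation(test = "character", decision = "character",
                 summary = "data.frame", pairwise = "list",
                 pValues = "numeric", notes = "character"))

setValidity("StatsReport", function(object) {
  p <- object@pValues
  if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
    return("p-values must lie in [0, 1]")
  for (m in object@pairwise) {
    if (!is.matrix(m)) return("pairwise entries must be matrices")
    off <- m[upper.tri(m) | lower.tri(m)]
    if (any(!is.na(off) & (off < 0 | off > 1)))
      return("pairwise p-values must lie in [0, 1]")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      return("pairwise p matrix must be symmetric")
  }
  TRUE
})
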