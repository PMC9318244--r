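# All randomness in the generator flows from one integer master seed
# through fixed counters, so every component (boundary, texture,
# background noise, speckle) draws from its own reproducible substream
# and the PL/NPL pair of a lesion shares boundary and texture exactly.
.substreamSeed <- function(seed, counter) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 69069 + as.double(counter) * 1013904223 + 17) %% 2147483647)
}

.withSubstream <- function(seed, counter, code) {
  withr::with_seed(.substreamSeed(seed, counter), code)
}

# Fractional Brownian field by spectral synthesis: white Gaussian noise
# filtered with radial amplitude f^-(hurst+1) (power spectrum f^-(2H+2),
# the 2-D fBm scaling), standardized to zero mean and unit sd.
.fbmField <- function(n, hurst, seed) {
  wn <- withr::with_seed(as.integer(seed), matrix(stats::rnorm(n * n), n, n))
  half <- n %/% 2L
  fx <- c(0:half, if (n - half - 1L > 0L) -((n - half - 1L):1L)) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- ifelse(f == 0, 0, f^(-(hurst + 1)))
  field <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (n * n)
  (field - mean(field)) / stats::sd(field)
}

#' Render an exact fractal or texture fixture
#'
#' Mathematical fixtures with known fractal dimension, used to anchor the
#' estimator: `"filled_square"` / `"constant_field"` (uniform full-frame
#' intensity; FD exactly 2 under exactly tiling scales),
#' `"sierpinski_carpet"` (FD = log 8 / log 3 = 1.8928; pixel (x, y),
#' 0-based, is background iff some base-3 digit pair of (x, y) is (1, 1)),
#' `"checkerboard"` (unit two-valued texture), and `"fbm_texture"`
#' (fractional Brownian field of given Hurst exponent, linearly scaled
#' into \[0, 255\]).
#'
#' @param kind one of `"filled_square"`, `"constant_field"`,
#'   `"sierpinski_carpet"`, `"checkerboard"`, `"fbm_texture"`.
#' @param side image side in pixels; for the carpet it must equal
#'   `3^depth` (and defaults to it).
#' @param depth carpet iteration depth.
#' @param foreground,background 8-bit levels; `foreground` is the uniform
#'   level of the constant kinds.
#' @param hurst Hurst exponent in (0, 1), fBm only.
#' @param seed integer seed, fBm only.
#' @return a [GrayImage-class] of `side` x `side` pixels.
#' @examples
#' renderFixture("sierpinski_carpet", depth = 1)  # 3x3, centre = background
#' @export
renderFixture <- function(kind = c("filled_square", "constant_field",
                                   "sierpinski_carpet", "checkerboard",
                                   "fbm_texture"),
                          side = NULL, depth = NULL,
                          foreground = 0, background = 255,
                          hurst = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "sierpinski_carpet") {
    if (is.null(depth)) stop("carpet requires a depth")
    if (is.null(side)) side <- 3L^depth
    if (side != 3L^depth)
      stop("carpet side must be exactly 3^depth = ", 3L^depth,
           " (got ", side, "); the digit rule is defined on that grid")
    digitIsOne <- function(level) ((0:(side - 1L)) %/% 3L^level) %% 3L == 1L
    hole <- Reduce(`|`, lapply(0:(depth - 1L), function(l) {
      d <- digitIsOne(l)
      outer(d, d, `&`)
    }))
    px <- matrix(foreground, side, side)
    px[hole] <- background
    return(GrayImage(px))
  }
  if (is.null(side)) stop("side is required")
  px <- switch(kind,
    filled_square  = ,
    constant_field = matrix(foreground, side, side),
    checkerboard   = matrix(ifelse(outer(1:side, 1:side, `+`) %% 2 == 0,
                                   foreground, background), side, side),
    fbm_texture    = {
      f <- .fbmField(side, hurst, seed)
      round((f - min(f)) / (max(f) - min(f)) * 255)
    })
  GrayImage(px)
}

#' Construct SyntheticLesionParams
#'
#' Defaults describe a mid-sized, mildly irregular lesion in a 256 x 256
#' frame; see [SyntheticLesionParams-class] for the meaning of each
#' control.
#'
#' @param imageWidth,imageHeight,baseRadius,irregularityAmplitude,harmonics
#'   geometry controls (pixels / dimensionless).
#' @param textureHurst,textureSd pigment-texture roughness and contrast.
#' @param lesionMean,backgroundMean 8-bit mean intensities.
#' @param illumination `"PL"` or `"NPL"`.
#' @param nplContrastFactor,specularNoiseDensity non-polarized rendering
#'   controls.
#' @param seed integer master seed.
#' @return a [SyntheticLesionParams-class].
#' @export
lesionParams <- function(imageWidth = 256L, imageHeight = 256L,
                         baseRadius = 80, irregularityAmplitude = 0.1,
                         harmonics = 48L, textureHurst = 0.5, textureSd = 20,
                         lesionMean = 70, backgroundMean = 200,
                         illumination = c("PL", "NPL"),
                         nplContrastFactor = 0.7,
                         specularNoiseDensity = 0.01, seed = 1L) {
  new("SyntheticLesionParams",
      imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight),
      baseRadius = baseRadius, irregularityAmplitude = irregularityAmplitude,
      harmonics = as.integer(harmonics), textureHurst = textureHurst,
      textureSd = textureSd, lesionMean = lesionMean,
      backgroundMean = backgroundMean, illumination = match.arg(illumination),
      nplContrastFactor = nplContrastFactor,
      specularNoiseDensity = specularNoiseDensity, seed = as.integer(seed))
}

setMethod("show", "SyntheticLesionParams", function(object) {
  cat(sprintf(paste0("SyntheticLesionParams: %dx%d, radius %.0f px, ",
                     "irregularity %.2f (%d harmonics), Hurst %.2f, %s, seed %d\n"),
              object@imageWidth, object@imageHeight, object@baseRadius,
              object@irregularityAmplitude, object@harmonics,
              object@textureHurst, object@illumination, object@seed))
})

# Seeded radial-Fourier boundary coefficients: modes k = 2..harmonics+1
# with 1/k amplitude decay and uniform phases.
.boundaryCoefs <- function(params) {
  .withSubstream(params@seed, 1L, {
    k <- 2L:(params@harmonics + 1L)
    list(k = k,
         a = stats::runif(length(k), -1, 1) / k,
         phi = stats::runif(length(k), 0, 2 * pi))
  })
}

#' Analytic lesion boundary curve
#'
#' The radial boundary r(theta) = R (1 + A sum_k a_k cos(k theta + phi_k))
#' with seeded coefficients a_k (1/k decay) and phases. Exposed so border
#' properties (e.g. perimeter growth with the irregularity amplitude) can
#' be asserted on the exact curve rather than on a rasterization.
#'
#' @param params a [SyntheticLesionParams-class].
#' @param nTheta number of evaluation angles.
#' @return data.frame with columns `theta` and `radius` (pixels).
#' @export
boundaryCurve <- function(params, nTheta = 720L) {
  cf <- .boundaryCoefs(params)
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  pert <- rowSums(vapply(seq_along(cf$k),
    function(i) cf$a[i] * cos(cf$k[i] * theta + cf$phi[i]),
    numeric(length(theta))))
  r <- params@baseRadius * (1 + params@irregularityAmplitude * pert)
  if (any(r <= 0))
    stop("boundary self-intersects (radius <= 0); lower irregularityAmplitude")
  data.frame(theta = theta, radius = r)
}

# Ground-truth lesion field shared by PL and NPL: logical mask from the
# radial boundary, plus the standardized fBm texture field.
.lesionField <- function(params) {
  w <- params@imageWidth; h <- params@imageHeight
  cf <- .boundaryCoefs(params)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  dy <- matrix(rep(seq_len(h) - cy, times = w), h, w)
  theta <- atan2(dy, dx)
  pert <- 0
  for (i in seq_along(cf$k))
    pert <- pert + cf$a[i] * cos(cf$k[i] * theta + cf$phi[i])
  r <- params@baseRadius * (1 + params@irregularityAmplitude * pert)
  if (any(r <= 0))
    stop("boundary self-intersects (radius <= 0); lower irregularityAmplitude")
  mask <- sqrt(dx^2 + dy^2) <= r
  n <- max(w, h)
  tex <- .fbmField(n, params@textureHurst, .substreamSeed(params@seed, 2L))
  list(mask = mask, texture = tex[seq_len(h), seq_len(w), drop = FALSE])
}

#' Ground-truth mask of a simulated lesion
#'
#' The analytic lesion mask the renderer fills — identical for the PL and
#' NPL renders of the same seed.
#'
#' @param params a [SyntheticLesionParams-class].
#' @return a [LesionMask-class].
#' @export
groundTruthMask <- function(params) LesionMask(.lesionField(params)$mask)

#' Render a simulated lesion photograph
#'
#' A dark lesion with seeded radial-Fourier border and fBm pigment texture
#' on a lighter, mildly noisy skin background. Under `illumination =
#' "NPL"` the lesion/background contrast is linearly compressed toward the
#' background by `nplContrastFactor` and seeded specular speckles
#' (saturated pixels) are superimposed, emulating the reflection-degraded
#' non-polarized photograph of the same lesion. Bit-reproducible for a
#' given parameter set.
#'
#' @param params a [SyntheticLesionParams-class].
#' @param output `"gray"` (default) for a [GrayImage-class], `"rgb"` for a
#'   height x width x 3 array with a melanin-like tint, convertible back
#'   through [toGrayscale()].
#' @return a [GrayImage-class] or an RGB array.
#' @export
renderLesion <- function(params, output = c("gray", "rgb")) {
  output <- match.arg(output)
  fld <- .lesionField(params)
  w <- params@imageWidth; h <- params@imageHeight
  img <- matrix(params@backgroundMean, h, w)
  img <- img + .withSubstream(params@seed, 3L,
                              matrix(stats::rnorm(h * w, sd = 2), h, w))
  img[fld$mask] <- params@lesionMean +
    params@textureSd * fld$texture[fld$mask]
  if (params@illumination == "NPL") {
    img <- params@backgroundMean + (img - params@backgroundMean) *
      params@nplContrastFactor
    nSpeck <- round(params@specularNoiseDensity * h * w)
    if (nSpeck > 0) {
      idx <- .withSubstream(params@seed, 4L, sample.int(h * w, nSpeck))
      img[idx] <- 255
    }
  }
  px <- pmin(pmax(round(img), 0), 255)  # matrix first: pmax/pmin keep dim
  if (output == "gray") return(GrayImage(px))
  rgb <- array(0, c(h, w, 3L))
  rgb[, , 1] <- px
  rgb[, , 2] <- floor(px * 0.75)
  rgb[, , 3] <- floor(px * 0.55)
  rgb
}

#' Default three-group lesion presets
#'
#' Parameter templates for the melanoma (MM), dysplastic nevus (DN) and
#' benign nevus (BN) groups: border irregularity and texture roughness
#' increase from BN to MM while everything else is shared. The values are
#' design choices for a plausible contrast between groups, not estimates
#' of any patient population.
#'
#' @return named list of argument lists for [lesionParams()].
#' @export
defaultPresets <- function() {
  list(MM = list(irregularityAmplitude = 0.35, textureHurst = 0.3),
       DN = list(irregularityAmplitude = 0.20, textureHurst = 0.5),
       BN = list(irregularityAmplitude = 0.05, textureHurst = 0.7))
}

#' Generate a paired-illumination lesion cohort
#'
#' For each group preset, draws `nPerGroup` lesions with per-lesion seeds
#' derived from the master seed and renders the PL/NPL pair of each
#' (sharing boundary and texture within a pair). With `render = FALSE`
#' only the parameter records are built.
#'
#' @param nPerGroup integer count per group, or a named vector aligned
#'   with `presets` for unbalanced designs.
#' @param presets named list of [lesionParams()] argument lists; defaults
#'   to [defaultPresets()].
#' @param seed master seed.
#' @param render render the images (`TRUE`) or return parameters only.
#' @param ... further arguments passed to every [lesionParams()] call
#'   (e.g. `imageWidth`).
#' @return list of records: `lesionId`, `group`, `seed`, `paramsPL`,
#'   `paramsNPL`, and when rendered `imagePL`, `imageNPL`.
#' @examples
#' ch <- generateCohort(2, seed = 7, render = FALSE)
#' length(ch)  # 2 lesions x 3 groups
#' @export
generateCohort <- function(nPerGroup, presets = defaultPresets(), seed = 1L,
                           render = TRUE, ...) {
  if (length(nPerGroup) == 1L)
    nPerGroup <- stats::setNames(rep(as.integer(nPerGroup), length(presets)),
                                 names(presets))
  stopifnot(all(nPerGroup >= 1L), all(names(presets) %in% names(nPerGroup)))
  extra <- list(...)
  out <- list()
  for (g in seq_along(presets)) {
    grp <- names(presets)[g]
    for (i in seq_len(nPerGroup[[grp]])) {
      lseed <- .substreamSeed(seed, g * 1000L + i)
      base <- utils::modifyList(utils::modifyList(presets[[g]], extra),
                                list(seed = lseed))
      pPL <- do.call(lesionParams, c(base, list(illumination = "PL")))
      pNPL <- do.call(lesionParams, c(base, list(illumination = "NPL")))
      rec <- list(lesionId = sprintf("%s_%02d", grp, i), group = grp,
                  seed = lseed, paramsPL = pPL, paramsNPL = pNPL)
      if (render) {
        rec$imagePL <- renderLesion(pPL)
        rec$imageNPL <- renderLesion(pNPL)
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}
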