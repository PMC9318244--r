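# Block-wise max/min reduction. Rows (or columns after transpose) are
# grouped into blocks of `eps`; a trailing partial block keeps its actual
# pixels. Offset loop is over eps shifted row subsets, so cost is
# O(eps * cells / eps) per direction.
.blockReduce <- function(m, eps, op = c("max", "min")) {
  op <- match.arg(op)
  reduce1 <- function(mat) {
    nr <- nrow(mat)
    bn <- ceiling(nr / eps)
    init <- if (op == "max") -Inf else Inf
    out <- matrix(init, bn, ncol(mat))
    f <- if (op == "max") pmax else pmin
    for (o in seq_len(eps)) {
      idx <- seq(o, nr, by = eps)
      if (!length(idx)) break
      g <- (idx - 1L) %/% eps + 1L
      out[g, ] <- f(out[g, , drop = FALSE], mat[idx, , drop = FALSE])
    }
    out
  }
  t(reduce1(t(reduce1(m))))
}

#' Per-scale intensity-difference sum I(eps)
#'
#' The image is covered by an eps x eps box grid anchored at the top-left
#' pixel. Each box contributes the difference between its maximum and
#' minimum pixel intensity plus one, so a flat box still counts 1; edge
#' boxes smaller than eps x eps enter with their actual pixels. The sum
#' over all boxes is the quantity whose log-log slope against 1/eps is the
#' intensity-difference fractal dimension.
#'
#' @param img a [GrayImage-class] (or bare numeric matrix).
#' @param eps box size in pixels, `2 <= eps <= min(dim)`.
#' @return the scalar sum I(eps).
#' @examples
#' boxIntensitySum(GrayImage(matrix(7, 64, 64)), 4)  # 256 flat boxes
#' @export
boxIntensitySum <- function(img, eps) {
  px <- if (is(img, "GrayImage")) pixels(img) else img
  eps <- as.integer(eps)
  if (eps < 2L) stop("eps must be >= 2")
  if (eps > min(dim(px)))
    stop("eps = ", eps, " exceeds the smaller image dimension ", min(dim(px)))
  mx <- .blockReduce(px, eps, "max")
  mn <- .blockReduce(px, eps, "min")
  sum(mx - mn + 1)
}

#' Estimate the intensity-difference box-counting fractal dimension
#'
#' Computes I(eps) for every scale of the series and fits an ordinary
#' least-squares regression of ln I(eps) on ln(1/eps); the slope is
#' reported as the fractal dimension. Deterministic: a single top-left
#' anchored grid per scale unless `gridOffsets > 1`, in which case I(eps)
#' is averaged over a `gridOffsets` x `gridOffsets` set of grid origin
#' shifts before the fit (off by default).
#'
#' @param img a [GrayImage-class].
#' @param scales a [ScaleSeries-class]; every scale must be at most half
#'   the smaller image dimension.
#' @param gridOffsets integer >= 1; number of grid origin shifts per axis.
#' @return an [FDResult-class].
#' @examples
#' img <- GrayImage(matrix(0, 512, 512))
#' fd(estimateFD(img, scaleSeries(c(4, 16, 64))))  # exactly 2
#' @export
estimateFD <- function(img, scales, gridOffsets = 1L) {
  px <- pixels(img)
  s <- scales(scales)
  if (any(s > min(dim(px)) / 2))
    stop("every scale must be <= min(image dims)/2 = ", min(dim(px)) / 2)
  gridOffsets <- as.integer(gridOffsets)
  I <- vapply(s, function(e) {
    if (gridOffsets <= 1L) return(boxIntensitySum(px, e))
    offs <- unique(round(seq(0L, e - 1L, length.out = gridOffsets)))
    vals <- outer(offs, offs, Vectorize(function(dr, dc)
      boxIntensitySum(px[(dr + 1L):nrow(px), (dc + 1L):ncol(px)], e)))
    mean(vals)
  }, numeric(1))
  x <- log(1 / s)
  if (length(unique(x)) < 2L) stop("zero-variance regressor: degenerate scales")
  fit <- stats::lm(log(I) ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected here
  if (is.nan(r2)) r2 <- 1  # zero residual and zero model variance: flat fit
  partial <- any(dim(px)[1] %% s != 0L | dim(px)[2] %% s != 0L)
  new("FDResult", fd = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = r2,
      perScale = data.frame(eps = s, I = I),
      metadata = list(scheme = scales@scheme, partialEdgeBoxes = partial,
                      gridOffsets = gridOffsets))
}

#' Scale-series constructors
#'
#' `scaleSeries()` wraps an explicit vector of box sizes.
#' `powerSeriesScales()` builds the shape-analysis series 4, 16, 64, 256,
#' ... (base 2, exponent step 2), keeping scales up to a quarter of the
#' smaller image dimension. `blockSeriesScales()` builds the
#' surface-analysis series for a square block: all integer divisors of the
#' block size between 2 and a quarter of the block, so every grid tiles
#' the block exactly.
#'
#' @param scales integer vector of box sizes.
#' @return a [ScaleSeries-class].
#' @export
scaleSeries <- function(scales) {
  new("ScaleSeries", scheme = "explicit", scales = as.integer(scales))
}

#' @rdname scaleSeries
#' @param dims image dimensions (vector of two) or a [GrayImage-class].
#' @param base,exponentStep geometric progression controls; the defaults
#'   give box sizes base^(exponentStep), base^(2 exponentStep), ...
#' @export
powerSeriesScales <- function(dims, base = 2, exponentStep = 2) {
  if (is(dims, "GrayImage")) dims <- dim(dims)
  if (min(dims) < 16) stop("image too small for the power series (min dim < 16)")
  cap <- min(dims) / 4
  expo <- seq(exponentStep, by = exponentStep,
              length.out = floor(log(cap, base) / exponentStep))
  s <- base^expo
  if (length(s) < 3L)
    stop("fewer than 3 power-series scales fit this image; ",
         "supply explicit scales with scaleSeries()")
  new("ScaleSeries", scheme = "power", scales = as.integer(s))
}

#' @rdname scaleSeries
#' @param blockSize side of the square block (ROI) in pixels, >= 8.
#' @export
blockSeriesScales <- function(blockSize) {
  blockSize <- as.integer(blockSize)
  if (blockSize < 8L) stop("blockSize must be >= 8")
  d <- seq_len(blockSize %/% 4L)
  d <- d[d >= 2L & blockSize %% d == 0L]
  if (length(d) < 3L)
    stop("fewer than 3 divisor scales in [2, blockSize/4] for block size ",
         blockSize, "; choose a block with more divisors")
  new("ScaleSeries", scheme = "block", scales = d)
}

#' @rdname ScaleSeries
#' @export
setMethod("scales", "ScaleSeries", function(object) object@scales)

setMethod("show", "ScaleSeries", function(object) {
  cat(sprintf("ScaleSeries (%s): %s\n", object@scheme,
              paste(object@scales, collapse = ", ")))
})

#' @rdname FDResult-accessors
#' @export
setMethod("fd", "FDResult", function(object) object@fd)

#' @rdname FDResult-accessors
#' @export
setMethod("rSquared", "FDResult", function(object) object@rSquared)

#' @rdname FDResult-accessors
#' @export
setMethod("perScale", "FDResult", function(object) object@perScale)

setMethod("show", "FDResult", function(object) {
  cat(sprintf("FDResult: FD = %.4f (R^2 = %.4f, %d scales, %s series)\n",
              object@fd, object@rSquared, nrow(object@perScale),
              object@metadata$scheme))
})
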