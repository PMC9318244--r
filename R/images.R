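#' Construct a GrayImage
#'
#' @param pixels numeric matrix of integer-valued intensities in \[0, 255\];
#'   rows are image rows (y), columns image columns (x).
#' @param mmPerPixel optional physical calibration in millimetres per pixel.
#' @return a [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(128, 8, 8))
#' dim(img)
#' @export
GrayImage <- function(pixels, mmPerPixel = NA_real_) {
  storage.mode(pixels) <- "double"  # uniform storage so renders compare bitwise
  new("GrayImage", pixels = pixels, mmPerPixel = as.numeric(mmPerPixel))
}

#' Construct a LesionMask
#'
#' @param pixels logical matrix, `TRUE` marking lesion pixels.
#' @return a [LesionMask-class].
#' @export
LesionMask <- function(pixels) new("LesionMask", pixels = pixels)

#' @rdname GrayImage
#' @export
setMethod("pixels", "GrayImage", function(object) object@pixels)

#' @rdname GrayImage
#' @export
setMethod("pixels", "LesionMask", function(object) object@pixels)

#' @rdname GrayImage
#' @export
setMethod("mmPerPixel", "GrayImage", function(object) object@mmPerPixel)

#' @rdname GrayImage
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @rdname GrayImage
#' @export
setMethod("dim", "LesionMask", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cal <- if (is.na(object@mmPerPixel)) "uncalibrated"
         else sprintf("%.4g mm/px", object@mmPerPixel)
  cat(sprintf("GrayImage %dx%d (HxW), range [%d, %d], %s\n",
              d[1], d[2], min(object@pixels), max(object@pixels), cal))
})

setMethod("show", "LesionMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LesionMask %dx%d, %d foreground px (%.1f%%)\n",
              d[1], d[2], sum(object@pixels),
              100 * mean(object@pixels)))
})

#' Read a lesion photograph from disk
#'
#' Reads an 8-bit PNG or TIFF photograph and returns it as a
#' [GrayImage-class]. RGB images are converted with [toGrayscale()]
#' (Rec. 709 luma); an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param mmPerPixel optional calibration attached to the result.
#' @return a [GrayImage-class].
#' @export
readLesionImage <- function(path, mmPerPixel = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "': PNG or TIFF expected"))
  arr <- round(arr * 255)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) return(toGrayscale(arr[, , 1:3], mmPerPixel))
    arr <- arr[, , 1L]
  }
  GrayImage(arr, mmPerPixel)
}

#' Write a GrayImage as an 8-bit grayscale PNG
#'
#' @param img a [GrayImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLesionImage <- function(img, path) {
  png::writePNG(pixels(img) / 255, path)
  invisible(path)
}
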