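#' @rdname GrayImage
#' @param object,x a package object.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname GrayImage
#' @export
setGeneric("mmPerPixel", function(object) standardGeneric("mmPerPixel"))

#' @rdname ScaleSeries
#' @export
setGeneric("scales", function(object) standardGeneric("scales"))

#' @rdname FDResult-accessors
#' @export
setGeneric("fd", function(object) standardGeneric("fd"))

#' @rdname FDResult-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname FDResult-accessors
#' @export
setGeneric("perScale", function(object) standardGeneric("perScale"))

#' @rdname MorphometryResult-accessors
#' @export
setGeneric("lesionArea", function(object) standardGeneric("lesionArea"))

#' @rdname MorphometryResult-accessors
#' @export
setGeneric("lesionPerimeter", function(object) standardGeneric("lesionPerimeter"))

#' @rdname ROISet-accessors
#' @export
setGeneric("origins", function(object) standardGeneric("origins"))

#' @rdname ROISet-accessors
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))

#' @rdname ROISet-accessors
#' @export
setGeneric("roiSize", function(object) standardGeneric("roiSize"))
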