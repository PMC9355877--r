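#' @rdname CalibratedImage-class
#' @param object,x a [CalibratedImage] (or other package object).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname CalibratedImage-class
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname CalibratedImage-class
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname ImageStack-class
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))

#' @rdname ImageStack-class
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))

#' @rdname ImageStack-class
#' @export
setGeneric("isTimeLapse", function(x) standardGeneric("isTimeLapse"))

#' @rdname GapResult-class
#' @export
setGeneric("gapCircles", function(x) standardGeneric("gapCircles"))
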