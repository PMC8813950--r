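#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("latAxis", function(x) standardGeneric("latAxis"))

#' @rdname gridValues
#' @export
setGeneric("lonAxis", function(x) standardGeneric("lonAxis"))

#' @rdname gridValues
#' @export
setGeneric("resolutionDeg", function(x) standardGeneric("resolutionDeg"))

#' @rdname gridValues
#' @export
setGeneric("variableName", function(x) standardGeneric("variableName"))

#' @rdname gridValues
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname aggregateMean
#' @export
setGeneric("aggregateMean", function(x, factor) standardGeneric("aggregateMean"))

#' @rdname aggregateMajor
#' @export
setGeneric("aggregateMajor", function(x, factor) standardGeneric("aggregateMajor"))
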