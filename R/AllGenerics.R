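#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small set of accessor generics shared by the axialFCS S4 containers.
#' Accessors are the supported way to reach slot contents; slot layout is
#' not part of the API.
#'
#' @param x an axialFCS object
#' @param ... further arguments passed to methods
#' @return the slot contents documented with each class
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("photonEvents", function(x, ...) standardGeneric("photonEvents"))

#' @rdname accessors
#' @export
setGeneric("kymoCounts", function(x, ...) standardGeneric("kymoCounts"))

#' @rdname accessors
#' @export
setGeneric("kymoRawCounts", function(x, ...) standardGeneric("kymoRawCounts"))

#' @rdname accessors
#' @export
setGeneric("lineTime", function(x) standardGeneric("lineTime"))

#' @rdname accessors
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setGeneric("zPixelEdges", function(x) standardGeneric("zPixelEdges"))

#' @rdname accessors
#' @export
setGeneric("dwellWeights", function(x) standardGeneric("dwellWeights"))

#' @rdname accessors
#' @export
setGeneric("ridgePositions", function(x) standardGeneric("ridgePositions"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("rawIntensity", function(x, ...) standardGeneric("rawIntensity"))

#' @rdname accessors
#' @export
setGeneric("backgroundIntensity", function(x, ...)
  standardGeneric("backgroundIntensity"))

#' @rdname accessors
#' @export
setGeneric("correctedIntensity", function(x, ...)
  standardGeneric("correctedIntensity"))

#' @rdname accessors
#' @export
setGeneric("gammaMean", function(x, ...) standardGeneric("gammaMean"))

#' @rdname accessors
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @rdname accessors
#' @export
setGeneric("corrValues", function(x, ...) standardGeneric("corrValues"))

#' @rdname accessors
#' @export
setGeneric("corrErrors", function(x, ...) standardGeneric("corrErrors"))

#' @rdname accessors
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))

#' @rdname accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname accessors
#' @export
setGeneric("aFactor", function(x) standardGeneric("aFactor"))

#' @rdname accessors
#' @export
setGeneric("omega0", function(x) standardGeneric("omega0"))

#' @rdname accessors
#' @export
setGeneric("obsAreas", function(x) standardGeneric("obsAreas"))

#' @rdname accessors
#' @export
setGeneric("kD", function(x) standardGeneric("kD"))

#' @rdname accessors
#' @export
setGeneric("bindingBeta", function(x) standardGeneric("bindingBeta"))

#' Evaluate a fitted smooth curve
#'
#' @param x a fitted curve object
#' @param t numeric times at which to evaluate
#' @return numeric vector of fitted values at \code{t}
#' @export
setGeneric("evalCurve", function(x, t) standardGeneric("evalCurve"))
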