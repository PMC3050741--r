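#' @include AllClasses.R
NULL

#' Accessors for network, fit and report objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{speciesNames}, \code{parameterNames}, \code{initialState},
#' \code{outputMap}, \code{reactionList}, \code{nSpecies}, \code{nParameters},
#' \code{nOutputs}, \code{referenceParams}, \code{bestFit}, \code{verdict},
#' \code{coefficientsOfVariation}, \code{acceptedEstimates},
#' \code{rankingOrder}.
#'
#' @param x the object
#' @return the requested component; see the class documentation for units
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' @rdname accessors
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' @rdname accessors
#' @export
setGeneric("outputMap", function(x) standardGeneric("outputMap"))

#' @rdname accessors
#' @export
setGeneric("reactionList", function(x) standardGeneric("reactionList"))

#' @rdname accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname accessors
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' @rdname accessors
#' @export
setGeneric("nOutputs", function(x) standardGeneric("nOutputs"))

#' @rdname accessors
#' @export
setGeneric("referenceParams", function(x) standardGeneric("referenceParams"))

#' @rdname accessors
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("coefficientsOfVariation",
           function(x) standardGeneric("coefficientsOfVariation"))

#' @rdname accessors
#' @export
setGeneric("acceptedEstimates", function(x) standardGeneric("acceptedEstimates"))

#' @rdname accessors
#' @export
setGeneric("rankingOrder", function(x) standardGeneric("rankingOrder"))
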