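#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; slot access in
#' user code should go through these.
#'
#' @param x an object of the documented class.
#' @return The slot contents named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(x) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("trajLengths", function(x) standardGeneric("trajLengths"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("atomGroups", function(x) standardGeneric("atomGroups"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))
#' @rdname accessors
#' @export
setGeneric("statePaths", function(x) standardGeneric("statePaths"))
#' @rdname accessors
#' @export
setGeneric("energyRecords", function(x) standardGeneric("energyRecords"))
#' @rdname accessors
#' @export
setGeneric("ticaEigenvalues", function(x) standardGeneric("ticaEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("ticaComponents", function(x) standardGeneric("ticaComponents"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))
#' @rdname accessors
#' @export
setGeneric("microToMacro", function(x) standardGeneric("microToMacro"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("emissionMeans", function(x) standardGeneric("emissionMeans"))
#' @rdname accessors
#' @export
setGeneric("emissionSds", function(x) standardGeneric("emissionSds"))
#' @rdname accessors
#' @export
setGeneric("idealizedPaths", function(x) standardGeneric("idealizedPaths"))
#' @rdname accessors
#' @export
setGeneric("thresholdBounds", function(x) standardGeneric("thresholdBounds"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("mfpt", function(x) standardGeneric("mfpt"))

#' Project data with a fitted model
#'
#' @param object a fitted model (e.g. \linkS4class{TicaModel}).
#' @param newdata data to project (a \linkS4class{FeatureMatrix} or matrix).
#' @param ... further arguments for methods.
#' @return projected coordinates.
#' @export
setGeneric("projectData", function(object, newdata, ...)
  standardGeneric("projectData"))
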