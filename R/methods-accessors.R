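#' @rdname accessors
#' @export
setMethod("transitionMatrix", "TransitionMatrix", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("lagTime", "TransitionMatrix", function(x) x@lag)
#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("trajLengths", "FeatureMatrix", function(x) x@trajLengths)
#' @rdname accessors
#' @export
setMethod("frameInterval", "FeatureMatrix", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("atomGroups", "ConformationEnsemble", function(x) x@atomGroups)
#' @rdname accessors
#' @export
setMethod("nFrames", "ConformationEnsemble", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("stateLabels", "ConformationEnsemble", function(x) x@stateLabels)

#' @rdname accessors
#' @export
setMethod("frameInterval", "FretTraceSet", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("statePaths", "FretTraceSet", function(x) x@statePaths)

#' @rdname accessors
#' @export
setMethod("energyRecords", "EnergyTable", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("ticaEigenvalues", "TicaModel", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("ticaComponents", "TicaModel", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("lagTime", "TicaModel", function(x) x@lag)

#' @rdname accessors
#' @export
setMethod("assignments", "MicrostateModel", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("clusterCenters", "MicrostateModel", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("stateCounts", "MicrostateModel", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("microToMacro", "MacrostateModel", function(x) x@microToMacro)
#' @rdname accessors
#' @export
setMethod("membership", "MacrostateModel", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("emissionMeans", "HmmFit", function(x) x@means)
#' @rdname accessors
#' @export
setMethod("emissionSds", "HmmFit", function(x) x@sds)
#' @rdname accessors
#' @export
setMethod("idealizedPaths", "HmmFit", function(x) x@paths)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "HmmFit", function(x) x@transition)

#' @rdname accessors
#' @export
setMethod("thresholdBounds", "StateThresholds", function(x) x@bounds)

#' @rdname accessors
#' @export
setMethod("populations", "KineticsSummary", function(x) x@populations)
#' @rdname accessors
#' @export
setMethod("mfpt", "KineticsSummary", function(x) x@mfpt)

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d states, lag %g %s, mode '%s'\n",
              nrow(object@matrix), object@lag, object@lagUnit, object@mode))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix: %d frames x %d features, %d trajectories, dt %g ns\n",
    nrow(object@values), ncol(object@values), length(object@trajLengths),
    object@frameInterval))
})

setMethod("show", "ConformationEnsemble", function(object) {
  cat(sprintf("ConformationEnsemble: %d frames, %d atoms, groups: %s\n",
              length(object@frames), nrow(object@frames[[1L]]),
              paste(names(object@atomGroups), collapse = ", ")))
})

setMethod("show", "FretTraceSet", function(object) {
  n <- vapply(object@traces, nrow, integer(1))
  cat(sprintf(
    "FretTraceSet: %d traces (%d-%d frames), frame interval %g s%s\n",
    length(object@traces), min(n), max(n), object@frameInterval,
    if (!is.null(object@statePaths)) ", with ground-truth paths" else ""))
})

setMethod("show", "EnergyTable", function(object) {
  rcols <- grep("^residue:", names(object@records), value = TRUE)
  cat(sprintf(
    "EnergyTable: %d records, %d microstates%s\n", nrow(object@records),
    length(unique(object@records$microstate)),
    if (length(rcols)) sprintf(", %d residue columns", length(rcols)) else ""))
})

setMethod("show", "TicaModel", function(object) {
  cat(sprintf("TicaModel: lag %d frames, %d/%d components kept\n",
              object@lag, object@nComponentsKept, ncol(object@components)))
  cat("  eigenvalues:",
      paste(sprintf("%.3f", head(object@eigenvalues, 5L)), collapse = " "),
      if (length(object@eigenvalues) > 5L) "..." else "", "\n")
})

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf("MicrostateModel: %d states, %d frames\n",
              nrow(object@centers),
              length(unlist(object@assignments, use.names = FALSE))))
})

setMethod("show", "MacrostateModel", function(object) {
  cat(sprintf("MacrostateModel (%s): %d microstates -> %d macrostates\n",
              object@methodTag, length(object@microToMacro), object@nMacro))
})

setMethod("show", "HmmFit", function(object) {
  cat(sprintf("HmmFit: %d states, logLik %.2f, BIC %.2f%s\n",
              object@nStates, object@logLik, object@bic,
              if (object@converged) "" else " (not converged)"))
  cat("  means:", paste(sprintf("%.3f", object@means), collapse = " "), "\n")
})

setMethod("show", "TransitionDensity", function(object) {
  cat(sprintf(
    "TransitionDensity: %d transitions, %dx%d grid, sigma %.3f\n",
    nrow(object@points), length(object@x), length(object@y), object@sigma))
})

setMethod("show", "StateThresholds", function(object) {
  cat("StateThresholds:\n")
  b <- object@bounds
  for (i in seq_len(nrow(b)))
    cat(sprintf("  E%d: %.3f - %.3f\n", i, b[i, 1L], b[i, 2L]))
})

setMethod("show", "KineticsSummary", function(object) {
  cat(sprintf(
    "KineticsSummary: %d macrostates, %d trajectories x %d steps (burn-in %d)\n",
    length(object@populations), object@nTraj, object@length, object@burnIn))
  cat("  populations:",
      paste(sprintf("%.3f", object@populations), collapse = " "), "\n")
})
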