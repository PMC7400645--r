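#' FRET trace generator specification
#'
#' A hidden Markov chain with Gaussian efficiency emissions; per-frame
#' efficiency is the hidden state's emission mean plus Gaussian noise,
#' clipped to [-0.2, 1.2] (real traces show shot-noise excursions outside
#' [0, 1], so clipping to the unit interval would distort the noise model).
#'
#' @param emissionMeans strictly increasing efficiency means in [0, 1].
#' @param emissionSds per-state emission sd (recycled), > 0.
#' @param chainMatrix row-stochastic hidden-chain transition matrix.
#' @param frameInterval seconds per frame (default 0.1, a 100 ms exposure).
#' @param traceLength frames per trace.
#' @param nTraces number of traces.
#' @param seed integer seed recorded in the spec.
#' @return A validated list of class \code{"FretGeneratorSpec"}.
#' @export
fretGeneratorSpec <- function(emissionMeans, emissionSds = 0.06, chainMatrix,
                              frameInterval = 0.1, traceLength = 1000L,
                              nTraces = 100L, seed = 1L) {
  n <- length(emissionMeans)
  if (is.unsorted(emissionMeans, strictly = TRUE))
    stop("emissionMeans must be strictly increasing")
  if (any(emissionMeans < 0 | emissionMeans > 1))
    stop("emissionMeans must lie in [0, 1]")
  emissionSds <- rep_len(emissionSds, n)
  if (any(emissionSds <= 0)) stop("emissionSds must be > 0")
  if (!isRowStochastic(chainMatrix) || nrow(chainMatrix) != n)
    stop("chainMatrix must be a row-stochastic n x n matrix")
  stopifnotScalar(frameInterval, "frameInterval", positive = TRUE)
  if (traceLength < 1L || nTraces < 1L)
    stop("traceLength and nTraces must be >= 1")
  structure(list(nStates = n, emissionMeans = emissionMeans,
                 emissionSds = emissionSds, chainMatrix = chainMatrix,
                 frameInterval = frameInterval,
                 traceLength = as.integer(traceLength),
                 nTraces = as.integer(nTraces), seed = as.integer(seed)),
            class = "FretGeneratorSpec")
}

#' Generate synthetic smFRET efficiency traces
#'
#' Samples hidden-state paths from the spec's chain (initial states from
#' its stationary distribution) and emits Gaussian-noised efficiencies
#' clipped to [-0.2, 1.2].  Ground-truth paths are returned in the trace
#' set for recovery scoring.
#'
#' @param spec a \code{\link{fretGeneratorSpec}} (its \code{seed} field
#'   drives all randomness; identical specs give bit-identical traces).
#' @return A \linkS4class{FretTraceSet} with per-frame \code{efficiency}
#'   columns and \code{statePaths}.
#' @export
generateFretTraces <- function(spec) {
  stopifnot(inherits(spec, "FretGeneratorSpec"))
  paths <- sampleDiscreteTrajectories(spec$chainMatrix, spec$nTraces,
                                      spec$traceLength,
                                      seed = subSeed(spec$seed, 1L))
  localSeed(subSeed(spec$seed, 2L), {
    traces <- lapply(paths, function(p) {
      e <- spec$emissionMeans[p] +
        rnorm(length(p), sd = spec$emissionSds[p])
      data.frame(efficiency = pmin(pmax(e, -0.2), 1.2))
    })
    new("FretTraceSet", traces = traces,
        frameInterval = spec$frameInterval,
        statePaths = lapply(paths, as.integer))
  })
}
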