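#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Row-stochastic transition probability matrix
#'
#' Container for a discrete-time Markov transition matrix \eqn{T(\Delta t)}
#' estimated (or constructed) at a fixed lag time, together with the raw
#' transition counts it was derived from.  Long-timescale dynamics follow by
#' propagating powers of the matrix, \eqn{P(n\Delta t) = [T(\Delta t)^T]^n
#' P(0)}.
#'
#' @slot matrix square numeric matrix; rows sum to 1.
#' @slot lag lag time of the matrix, in the unit given by \code{lagUnit}.
#' @slot lagUnit character, e.g. \code{"ns"} or \code{"steps"}.
#' @slot counts transition count matrix (may be empty for constructed
#'   matrices).
#' @slot mode estimation mode: \code{"symmetrized"} (reversible, count
#'   symmetrization), \code{"raw"}, or \code{"constructed"}.
#'
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(matrix = "matrix", lag = "numeric", lagUnit = "character",
                 counts = "matrixOrNULL", mode = "character"),
  prototype(lag = 1, lagUnit = "steps", counts = NULL, mode = "constructed"))

setValidity("TransitionMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(m < -1e-12)) return("negative transition probabilities")
  if (any(abs(rowSums(m) - 1) > 1e-9)) return("rows must sum to 1")
  if (length(object@lag) != 1L || object@lag <= 0) return("lag must be > 0")
  TRUE
})

#' Feature matrix (frames x features)
#'
#' Per-frame feature values for one or more trajectories, stored
#' contiguously with trajectory lengths recording the boundaries.  Feature
#' names live in the column names.
#'
#' @slot values numeric matrix, frames x features, no missing values.
#' @slot frameInterval time between consecutive frames (ns).
#' @slot trajLengths integer vector partitioning the rows into trajectories.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", frameInterval = "numeric",
                 trajLengths = "integer"))

setValidity("FeatureMatrix", function(object) {
  if (anyNA(object@values)) return("values must not contain NA")
  if (sum(object@trajLengths) != nrow(object@values))
    return("trajLengths must partition the rows")
  if (any(object@trajLengths < 1L)) return("empty trajectory")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

#' Toy 3D conformational ensemble with labelled atom groups
#'
#' A list of coordinate frames (atoms x 3, in Angstrom) plus a role ->
#' atom-index map naming the groups used by the structural order
#' parameters: large-domain and small-domain C-alpha atoms, hinge atoms,
#' ligand heavy atoms, the FRET probe pair, the four hinge hydrogen-bond
#' donor/acceptor pairs and the three small-domain pocket groups (helix V,
#' helix VI, strand J).
#'
#' @slot frames list of numeric matrices (nAtoms x 3), identical dims.
#' @slot atomGroups named list of integer index vectors.
#' @slot stateLabels optional per-frame state label (character).
#'
#' @exportClass ConformationEnsemble
setClass("ConformationEnsemble",
  representation(frames = "list", atomGroups = "list",
                 stateLabels = "character"),
  prototype(stateLabels = character()))

setValidity("ConformationEnsemble", function(object) {
  if (!length(object@frames)) return("at least one frame required")
  n <- nrow(object@frames[[1L]])
  ok <- vapply(object@frames, function(f)
    is.matrix(f) && ncol(f) == 3L && nrow(f) == n, logical(1))
  if (!all(ok)) return("all frames must be nAtoms x 3 matrices")
  idx <- unlist(object@atomGroups, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    return("atom group index out of bounds")
  if (!is.null(object@atomGroups$probe_pair) &&
      length(object@atomGroups$probe_pair) != 2L)
    return("probe_pair must contain exactly 2 atoms")
  if (!is.null(object@atomGroups$hbond_pairs) &&
      length(object@atomGroups$hbond_pairs) != 8L)
    return("hbond_pairs must contain 4 donor-acceptor pairs (8 atoms)")
  if (length(object@stateLabels) &&
      length(object@stateLabels) != length(object@frames))
    return("stateLabels must match the number of frames")
  TRUE
})

#' Set of single-molecule FRET traces
#'
#' Each trace is either a pair of per-frame donor/acceptor intensities or a
#' precomputed per-frame efficiency.  Ground-truth hidden state paths (for
#' synthetic traces) ride along for recovery scoring.
#'
#' @slot traces list; each element a data.frame with columns
#'   \code{donor}/\code{acceptor} or a column \code{efficiency}.
#' @slot frameInterval seconds per frame (default 0.1 s, i.e. a 100 ms
#'   exposure).
#' @slot statePaths optional list of integer hidden-state paths.
#'
#' @exportClass FretTraceSet
setClass("FretTraceSet",
  representation(traces = "list", frameInterval = "numeric",
                 statePaths = "listOrNULL"),
  prototype(frameInterval = 0.1, statePaths = NULL))

setValidity("FretTraceSet", function(object) {
  if (!length(object@traces)) return("at least one trace required")
  for (tr in object@traces) {
    if (!is.data.frame(tr)) return("each trace must be a data.frame")
    hasI <- all(c("donor", "acceptor") %in% names(tr))
    hasE <- "efficiency" %in% names(tr)
    if (!hasI && !hasE)
      return("trace needs donor+acceptor or efficiency columns")
    if (hasI && any(tr$donor < 0 | tr$acceptor < 0, na.rm = TRUE))
      return("intensities must be >= 0")
    if (hasE && any(!is.finite(tr$efficiency)))
      return("efficiencies must be finite")
  }
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (!is.null(object@statePaths) &&
      length(object@statePaths) != length(object@traces))
    return("statePaths must match traces")
  TRUE
})

#' Per-frame binding-energy table
#'
#' Long-format records of per-frame total binding energies (kJ/mol), keyed
#' by microstate, optionally with per-residue decomposition columns
#' (named \code{residue:<id>}) that sum to the total.
#'
#' @slot records data.frame with columns \code{microstate}, \code{frame},
#'   \code{total}, and optional \code{residue:*} columns.
#'
#' @exportClass EnergyTable
setClass("EnergyTable", representation(records = "data.frame"))

setValidity("EnergyTable", function(object) {
  rec <- object@records
  need <- c("microstate", "frame", "total")
  if (!all(need %in% names(rec)))
    return("records needs columns microstate, frame, total")
  rcols <- grep("^residue:", names(rec), value = TRUE)
  if (length(rcols)) {
    s <- rowSums(as.matrix(rec[, rcols, drop = FALSE]))
    if (any(abs(s - rec$total) > 1e-6))
      return("per-residue energies must sum to total within 1e-6")
  }
  TRUE
})

#' Time-structure independent component analysis (tICA) model
#'
#' Solution of the generalized eigenproblem of the symmetrized time-lagged
#' covariance against the instantaneous covariance; columns of
#' \code{components} are normalized in the instantaneous-covariance metric
#' and eigenvalues are lag-time autocorrelations sorted descending.
#'
#' @slot lag lag in frames.
#' @slot means per-feature means removed before the covariances.
#' @slot components eigenvector matrix (features x kept components).
#' @slot eigenvalues autocorrelation eigenvalues, sorted descending.
#' @slot nComponentsKept number of components retained for projection.
#'
#' @exportClass TicaModel
setClass("TicaModel",
  representation(lag = "integer", means = "numeric", components = "matrix",
                 eigenvalues = "numeric", nComponentsKept = "integer"))

setValidity("TicaModel", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be sorted descending")
  if (object@nComponentsKept > ncol(object@components))
    return("nComponentsKept exceeds available components")
  TRUE
})

#' Microstate decomposition (k-center clustering)
#'
#' Cluster centers in tICA space plus per-frame assignments.  After
#' pruning, \code{activeStateMap} records the relabelling from the original
#' to the retained states (NA for removed states).
#'
#' @slot centers matrix of cluster centers (states x dims).
#' @slot assignments list of integer vectors (1-based state per frame).
#' @slot counts frames per state.
#' @slot activeStateMap integer relabelling old -> new, NA where pruned.
#'
#' @exportClass MicrostateModel
setClass("MicrostateModel",
  representation(centers = "matrix", assignments = "list",
                 counts = "integer", activeStateMap = "integer"))

setValidity("MicrostateModel", function(object) {
  k <- nrow(object@centers)
  a <- unlist(object@assignments, use.names = FALSE)
  if (length(a) && (min(a) < 1L || max(a) > k))
    return("assignments reference unknown states")
  if (length(object@counts) != k) return("counts length must match centers")
  TRUE
})

#' Macrostate lumping of a microstate model
#'
#' Crisp microstate-to-macrostate assignment plus the fuzzy membership
#' matrix it was derived from (PCCA+-style rows sum to 1).
#'
#' @slot microToMacro integer macrostate per microstate.
#' @slot nMacro number of macrostates.
#' @slot membership fuzzy membership matrix (micro x macro).
#' @slot methodTag character tag of the lumping method.
#'
#' @exportClass MacrostateModel
setClass("MacrostateModel",
  representation(microToMacro = "integer", nMacro = "integer",
                 membership = "matrix", methodTag = "character"))

setValidity("MacrostateModel", function(object) {
  if (any(object@microToMacro < 1L | object@microToMacro > object@nMacro))
    return("microToMacro out of range")
  if (nrow(object@membership) != length(object@microToMacro))
    return("membership rows must match microstates")
  if (any(abs(rowSums(object@membership) - 1) > 1e-6))
    return("membership rows must sum to 1")
  TRUE
})

#' Gaussian-emission hidden Markov model fit
#'
#' Maximum-likelihood Baum-Welch fit to FRET efficiency traces; states are
#' reported with emission means sorted ascending, and \code{paths} holds the
#' Viterbi-idealized state sequence of each trace.
#'
#' @slot nStates number of hidden states.
#' @slot means,sds Gaussian emission parameters (efficiency units).
#' @slot transition row-stochastic hidden-chain matrix.
#' @slot initial initial state distribution.
#' @slot logLik final log-likelihood.
#' @slot bic Bayesian information criterion of the fit.
#' @slot paths list of integer Viterbi paths, one per trace.
#' @slot converged logical.
#'
#' @exportClass HmmFit
setClass("HmmFit",
  representation(nStates = "integer", means = "numeric", sds = "numeric",
                 transition = "matrix", initial = "numeric",
                 logLik = "numeric", bic = "numeric", paths = "list",
                 converged = "logical"))

setValidity("HmmFit", function(object) {
  if (is.unsorted(object@means)) return("means must be sorted ascending")
  if (!isRowStochastic(object@transition, 1e-6))
    return("transition must be row-stochastic")
  if (any(object@sds <= 0)) return("sds must be > 0")
  TRUE
})

#' Transition density plot (TDP)
#'
#' Change points of idealized FRET traces as (efficiency before, efficiency
#' after) pairs, dressed with isotropic 2D Gaussians on a grid; the density
#' integrates to the number of transitions.
#'
#' @slot points n x 2 matrix of (E_before, E_after).
#' @slot x,y grid coordinates.
#' @slot density matrix of dressed density values (length(x) x length(y)).
#' @slot sigma dressing width (efficiency units).
#'
#' @exportClass TransitionDensity
setClass("TransitionDensity",
  representation(points = "matrix", x = "numeric", y = "numeric",
                 density = "matrix", sigma = "numeric"))

setValidity("TransitionDensity", function(object) {
  if (ncol(object@points) != 2L && nrow(object@points) > 0L)
    return("points must have 2 columns")
  if (any(object@density < -1e-12)) return("density must be >= 0")
  TRUE
})

#' Per-state FRET efficiency classification thresholds
#'
#' Non-overlapping, increasing (low, high) efficiency intervals, one per
#' state, as set by the full-width-half-height of the fitted state
#' Gaussians.
#'
#' @slot bounds matrix with columns \code{low}, \code{high}, rows ordered by
#'   increasing center.
#'
#' @exportClass StateThresholds
setClass("StateThresholds", representation(bounds = "matrix"))

setValidity("StateThresholds", function(object) {
  b <- object@bounds
  if (ncol(b) != 2L) return("bounds must have columns low, high")
  if (any(b[, 2L] <= b[, 1L])) return("each interval needs high > low")
  if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L]))
    return("intervals must be non-overlapping and increasing")
  TRUE
})

#' Macrostate kinetics summary from Monte-Carlo propagation
#'
#' Stationary populations and mean first passage times of the lumped
#' network, each a mean with a standard deviation over the Monte-Carlo
#' trajectories.
#'
#' @slot populations,populationSd per-macrostate occupancy mean and sd.
#' @slot mfpt,mfptSd macro x macro MFPT mean and sd (time units); diagonal 0.
#' @slot mfptN number of trajectories contributing to each MFPT cell.
#' @slot nTraj,length,burnIn Monte-Carlo settings (steps).
#' @slot timeUnit time per step used in reporting.
#'
#' @exportClass KineticsSummary
setClass("KineticsSummary",
  representation(populations = "numeric", populationSd = "numeric",
                 mfpt = "matrix", mfptSd = "matrix", mfptN = "matrix",
                 nTraj = "integer", length = "integer", burnIn = "integer",
                 timeUnit = "numeric"))

setValidity("KineticsSummary", function(object) {
  if (abs(sum(object@populations) - 1) > 1e-6)
    return("populations must sum to 1")
  if (any(diag(object@mfpt) != 0, na.rm = TRUE))
    return("MFPT diagonal must be 0")
  TRUE
})
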