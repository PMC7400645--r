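#' Kinetic network specification
#'
#' Describes a coarse metastable kinetic network from which a reversible
#' microstate transition matrix can be constructed: macrostate stationary
#' populations, the number of microstates inside each macrostate, and
#' intra-/inter-macrostate transition propensities.  The default fixtures
#' mimic an eight-state two-domain ligand-binding network in which
#' intra-cluster (opening/closing) transitions are fast and inter-cluster
#' (ligand relocation) transitions are slow.
#'
#' @param macroPopulations numeric vector of stationary macrostate
#'   populations; must sum to 1 within 1e-12 after an explicit normalization
#'   check (no silent rescaling).
#' @param nMicroPerMacro integer, microstates per macrostate (recycled).
#' @param intraRate proposal probability per step for transitions between
#'   microstates of the same macrostate.
#' @param interRateMatrix symmetric nonnegative macro x macro propensity
#'   matrix; entry (a,b) is the per-step proposal rate between microstates
#'   of macrostates a and b (diagonal ignored).
#' @param lagUnit time per chain step, in ns.
#' @param macroNames optional character names for the macrostates.
#'
#' @return A validated list of class \code{"KineticNetworkSpec"}.
#' @export
kineticNetworkSpec <- function(macroPopulations, nMicroPerMacro = 1L,
                               intraRate = 0.3, interRateMatrix,
                               lagUnit = 1, macroNames = NULL) {
  nMacro <- length(macroPopulations)
  if (nMacro < 2L) stop("need at least 2 macrostates")
  if (any(macroPopulations <= 0))
    stop("macrostate populations must be > 0")
  if (abs(sum(macroPopulations) - 1) > 1e-12)
    stop("macroPopulations must sum to 1 within 1e-12")
  nMicroPerMacro <- rep_len(as.integer(nMicroPerMacro), nMacro)
  if (any(nMicroPerMacro < 1L)) stop("nMicroPerMacro must be >= 1")
  if (missing(interRateMatrix)) {
    interRateMatrix <- matrix(0.05, nMacro, nMacro)
  }
  if (!is.matrix(interRateMatrix) || any(dim(interRateMatrix) != nMacro))
    stop("interRateMatrix must be nMacro x nMacro")
  if (any(interRateMatrix < 0) || intraRate < 0)
    stop("propensities must be >= 0")
  if (any(abs(interRateMatrix - t(interRateMatrix)) > 1e-12))
    stop("interRateMatrix must be symmetric")
  if (is.null(macroNames)) macroNames <- paste0("M", seq_len(nMacro))
  structure(list(nMacro = nMacro, macroPopulations = macroPopulations,
                 nMicroPerMacro = nMicroPerMacro, intraRate = intraRate,
                 interRateMatrix = interRateMatrix, lagUnit = lagUnit,
                 macroNames = macroNames),
            class = "KineticNetworkSpec")
}

## Reversible Metropolis chain: symmetric proposal Q (zero diagonal),
## acceptance min(1, pi_j/pi_i).  Rescales Q uniformly if any row would
## overflow, keeping detailed balance exact: pi_i T_ij = pi_j T_ji.
metropolisMatrix <- function(pi, Q, maxRowSum = 0.9) {
  n <- length(pi)
  diag(Q) <- 0
  A <- Q * pmin(1, outer(pi, pi, function(a, b) b / a))
  rs <- max(rowSums(A))
  if (rs > maxRowSum) A <- A * (maxRowSum / rs)
  diag(A) <- 1 - rowSums(A)
  A
}

#' Construct a reversible microstate transition matrix from a network spec
#'
#' Builds a row-stochastic microstate matrix whose stationary distribution,
#' aggregated per macrostate, equals the spec's macrostate populations
#' exactly (to numerical precision).  Microstate stationary weights within
#' each macrostate are drawn once from a Gamma(5,1) split (seeded), so
#' microstates are genuinely unequal; the matrix itself is a
#' Metropolis-style detailed-balance chain over a proposal graph with
#' all-to-all intra-macrostate edges at \code{intraRate} and inter-edges at
#' the spec's propensities.  Reversibility guarantees a real eigenvalue
#' spectrum, so implied timescales are well-defined.
#'
#' @param spec a \code{\link{kineticNetworkSpec}}.
#' @param seed integer seed for the microstate weight split.
#' @return A \linkS4class{TransitionMatrix} with attributes
#'   \code{microToMacro} (integer macro label per microstate) and
#'   \code{stationary} (the exact microstate stationary vector) stored in
#'   the object's metadata via \code{attr}.
#' @export
buildNetworkMatrix <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "KineticNetworkSpec"))
  nMicro <- sum(spec$nMicroPerMacro)
  macroOf <- rep(seq_len(spec$nMacro), spec$nMicroPerMacro)
  piMicro <- localSeed(seed, {
    unlist(lapply(seq_len(spec$nMacro), function(m) {
      n <- spec$nMicroPerMacro[m]
      w <- if (n == 1L) 1 else stats::rgamma(n, shape = 5)
      spec$macroPopulations[m] * w / sum(w)
    }), use.names = FALSE)
  })
  Q <- matrix(0, nMicro, nMicro)
  intra <- outer(macroOf, macroOf, "==")
  Q[intra] <- spec$intraRate
  inter <- spec$interRateMatrix[cbind(macroOf[row(Q)], macroOf[col(Q)])]
  Q[!intra] <- inter[!intra]
  diag(Q) <- 0
  Tm <- metropolisMatrix(piMicro, Q)
  obj <- new("TransitionMatrix", matrix = Tm, lag = spec$lagUnit,
             lagUnit = "ns", counts = NULL, mode = "constructed")
  attr(obj@matrix, "microToMacro") <- macroOf
  attr(obj@matrix, "stationary") <- piMicro
  obj
}

#' Sample discrete microstate trajectories from a transition matrix
#'
#' @param T a \linkS4class{TransitionMatrix} or a row-stochastic matrix.
#' @param nTraj number of trajectories.
#' @param length trajectory length in steps (>= 1).
#' @param seed integer; the same seed reproduces bit-identical output.
#' @param start optional initial state(s) (recycled over trajectories);
#'   default samples initial states from the stationary distribution.
#' @return A list of integer vectors (class \code{"MicrostateTrajectories"}).
#' @export
sampleDiscreteTrajectories <- function(T, nTraj, length, seed = 1L,
                                       start = NULL) {
  Tm <- if (is(T, "TransitionMatrix")) T@matrix else T
  if (!isRowStochastic(Tm)) stop("T must be row-stochastic")
  if (length < 1L) stop("'length' must be >= 1")
  n <- nrow(Tm)
  cumT <- t(apply(Tm, 1L, cumsum))
  cumT[, n] <- 1
  localSeed(seed, {
    cur <- if (is.null(start)) {
      pi0 <- stationaryDistribution(Tm)
      sample.int(n, nTraj, replace = TRUE, prob = pi0)
    } else rep_len(as.integer(start), nTraj)
    out <- matrix(0L, nrow = length, ncol = nTraj)
    out[1L, ] <- cur
    if (length > 1L) for (t in 2L:length) {
      u <- runif(nTraj)
      cur <- 1L + as.integer(rowSums(cumT[cur, , drop = FALSE] < u))
      out[t, ] <- cur
    }
    trajs <- lapply(seq_len(nTraj), function(j) out[, j])
    class(trajs) <- "MicrostateTrajectories"
    trajs
  })
}

#' Ground-truth macrostate model of a constructed network matrix
#'
#' Wraps the generating microstate-to-macrostate assignment stored in a
#' matrix built by \code{\link{buildNetworkMatrix}} as a crisp
#' \linkS4class{MacrostateModel}, for use as the reference lumping in
#' recovery experiments.
#'
#' @param T a \linkS4class{TransitionMatrix} from
#'   \code{\link{buildNetworkMatrix}}.
#' @return A \linkS4class{MacrostateModel}.
#' @export
generatorMacrostates <- function(T) {
  stopifnot(is(T, "TransitionMatrix"))
  m2m <- attr(T@matrix, "microToMacro")
  if (is.null(m2m)) stop("T carries no generator macrostate labels")
  k <- max(m2m)
  new("MacrostateModel", microToMacro = as.integer(m2m),
      nMacro = as.integer(k),
      membership = diag(k)[m2m, , drop = FALSE], methodTag = "generator")
}
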