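asTMatrix <- function(T) {
  Tm <- if (is(T, "TransitionMatrix")) T@matrix else as.matrix(T)
  if (!isRowStochastic(Tm)) stop("T must be row-stochastic")
  Tm
}

#' Stationary distribution of an irreducible transition matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum 1; all entries
#' strictly positive.  Errors on a reducible matrix.
#'
#' @param T a \linkS4class{TransitionMatrix} or row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationaryDistribution <- function(T) {
  Tm <- asTMatrix(T)
  g <- igraph::graph_from_adjacency_matrix(Tm > 0, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("transition matrix is reducible; restrict to a strongly ",
         "connected component first")
  e <- eigen(t(Tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  pi0 <- v / sum(v)
  if (any(pi0 <= 0)) pi0 <- abs(pi0) / sum(abs(pi0))
  res <- max(abs(drop(pi0 %*% Tm) - pi0))
  if (res > 1e-8) stop("failed to solve stationary distribution ",
                       "(residual ", format(res), ")")
  pi0
}

#' Lump microstates into metastable macrostates (PCCA+)
#'
#' Perron-cluster cluster analysis on a reversible transition matrix: the
#' top \code{nMacro} right eigenvectors span a simplex whose vertices
#' correspond to the metastable sets; the deterministic vertex-seeded
#' inner-simplex search of the most spread eigenvector rows yields the
#' linear transformation to (near-)nonnegative memberships, which are
#' clipped, row-normalized and crisped by maximal membership.
#'
#' @param T a reversible \linkS4class{TransitionMatrix} (symmetrized or
#'   constructed mode), irreducible.
#' @param nMacro number of macrostates (>= 1).
#' @return A \linkS4class{MacrostateModel}.
#' @export
lumpPcca <- function(T, nMacro) {
  Tm <- asTMatrix(T)
  n <- nrow(Tm)
  nMacro <- as.integer(nMacro)
  if (nMacro < 1L || nMacro > n) stop("nMacro must be in 1..nStates")
  if (nMacro == 1L) {
    return(new("MacrostateModel", microToMacro = rep(1L, n),
               nMacro = 1L, membership = matrix(1, n, 1L),
               methodTag = "pcca+"))
  }
  eg <- sortedEigen(Tm, vectors = TRUE)
  vals <- Re(eg$values)
  if (length(vals) > nMacro &&
      abs(vals[nMacro] - vals[nMacro + 1L]) < 1e-10)
    stop("eigenvalue degeneracy at the spectral cut; choose a different ",
         "nMacro")
  X <- Re(eg$vectors[, seq_len(nMacro), drop = FALSE])
  X[, 1L] <- 1
  ## inner-simplex vertex search (deterministic, ties to lowest index)
  ind <- integer(nMacro)
  Y <- X
  ind[1L] <- which.max(rowNorms(Y))
  Y <- sweep(Y, 2L, Y[ind[1L], ])
  for (j in seq_len(nMacro - 1L) + 1L) {
    dn <- rowNorms(Y)
    ind[j] <- which.max(dn)
    v <- Y[ind[j], ] / dn[ind[j]]
    Y <- Y - (Y %*% v) %*% t(v)
  }
  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- rowNormalize(chi)
  crisp <- max.col(chi, ties.method = "first")
  if (length(unique(crisp)) < nMacro)
    stop("empty macrostate after crisp assignment; choose a different ",
         "nMacro")
  new("MacrostateModel", microToMacro = as.integer(crisp),
      nMacro = nMacro, membership = chi, methodTag = "pcca+")
}

#' Membership-weighted coarse-grained transition matrix
#'
#' \eqn{T_c = (\chi^T \Pi \chi)^{-1} \chi^T \Pi T \chi} with \eqn{\Pi =
#' diag(\pi)}; preserves the slow spectrum of a good lumping.
#'
#' @param T microstate \linkS4class{TransitionMatrix}.
#' @param macro a \linkS4class{MacrostateModel}.
#' @return Row-stochastic macro-level matrix.
#' @export
coarseGrainMatrix <- function(T, macro) {
  Tm <- asTMatrix(T)
  pi0 <- stationaryDistribution(Tm)
  chi <- macro@membership
  M <- solve(crossprod(chi, pi0 * chi), crossprod(chi, pi0 * (Tm %*% chi)))
  rowNormalize(pmax(M, 0))
}

## entry points into macrostate a: t with m[t]==a and (t==1 or m[t-1]!=a)
entryPoints <- function(m, a) {
  isA <- m == a
  which(isA & c(TRUE, !isA[-length(isA)]))
}

#' Macrostate populations and MFPTs by Monte-Carlo propagation
#'
#' Samples \code{nTraj} microstate chains from \code{T}, discards the
#' burn-in, lumps frames into macrostates and reports per-macrostate
#' occupancies and mean first passage times.  MFPT(a,b) in each trajectory
#' is the mean, over all entries into a, of the time from that entry to
#' the first subsequent entry into b (incomplete passages at the
#' trajectory end are dropped); the summary is the mean and sd over
#' trajectories, in time units of the matrix lag.
#'
#' @param T microstate \linkS4class{TransitionMatrix}.
#' @param macro a \linkS4class{MacrostateModel} for its states.
#' @param nTraj number of Monte-Carlo trajectories (default 100).
#' @param length steps per trajectory.
#' @param burnIn steps discarded from the start (default \code{length/3},
#'   mirroring discarding the first third as equilibration).
#' @param seed integer seed.
#' @param macroNames optional macrostate names for the report.
#' @return A \linkS4class{KineticsSummary}.
#' @export
mcKinetics <- function(T, macro, nTraj = 100L, length = 10000L,
                       burnIn = NULL, seed = 1L, macroNames = NULL) {
  stopifnot(is(T, "TransitionMatrix"), is(macro, "MacrostateModel"))
  if (is.null(burnIn)) burnIn <- as.integer(floor(length / 3))
  if (burnIn >= length) stop("burnIn must be smaller than length")
  nMacro <- macro@nMacro
  trajs <- sampleDiscreteTrajectories(T, nTraj, length, seed = seed)
  macroTrajs <- lapply(trajs, function(a)
    macro@microToMacro[a][(burnIn + 1L):length])
  nKeep <- as.integer(length) - as.integer(burnIn)
  occ <- t(vapply(macroTrajs, function(m)
    tabulate(m, nbins = nMacro) / nKeep, numeric(nMacro)))
  mf <- array(NA_real_, c(nMacro, nMacro, nTraj))
  for (k in seq_len(nTraj)) {
    m <- macroTrajs[[k]]
    idxByMacro <- split(seq_along(m), factor(m, levels = seq_len(nMacro)))
    for (a in seq_len(nMacro)) {
      ent <- entryPoints(m, a)
      if (!length(ent)) next
      for (b in seq_len(nMacro)) {
        if (a == b) next
        bi <- idxByMacro[[b]]
        if (!length(bi)) next
        nxt <- bi[findInterval(ent, bi) + 1L]
        dt <- nxt - ent
        dt <- dt[!is.na(dt)]
        if (length(dt)) mf[a, b, k] <- mean(dt)
      }
    }
  }
  if (is.null(macroNames)) macroNames <- paste0("M", seq_len(nMacro))
  tu <- T@lag
  mfptMean <- apply(mf, c(1L, 2L), mean, na.rm = TRUE) * tu
  mfptSd <- apply(mf, c(1L, 2L), sd, na.rm = TRUE) * tu
  mfptN <- apply(!is.na(mf), c(1L, 2L), sum)
  diag(mfptMean) <- 0; diag(mfptSd) <- 0
  mfptMean[is.nan(mfptMean)] <- NA_real_
  dimnames(mfptMean) <- dimnames(mfptSd) <- dimnames(mfptN) <-
    list(macroNames, macroNames)
  new("KineticsSummary",
      populations = setNames(colMeans(occ), macroNames),
      populationSd = setNames(apply(occ, 2L, sd), macroNames),
      mfpt = mfptMean, mfptSd = mfptSd, mfptN = mfptN,
      nTraj = as.integer(nTraj), length = as.integer(length),
      burnIn = as.integer(burnIn), timeUnit = tu)
}

#' Exact mean first passage times to a macrostate (linear solve)
#'
#' Solves the first-passage system \eqn{m = 0} on the target microstates
#' and \eqn{m = \tau + T m} elsewhere — the closed-form oracle for
#' \code{\link{mcKinetics}}.
#'
#' @param T microstate \linkS4class{TransitionMatrix}.
#' @param targetMacro target macrostate index.
#' @param macro a \linkS4class{MacrostateModel}.
#' @return Numeric vector: MFPT from every microstate to the target set,
#'   in time units of the matrix lag.
#' @export
mfptExact <- function(T, targetMacro, macro) {
  Tm <- asTMatrix(T)
  B <- which(macro@microToMacro == targetMacro)
  if (!length(B)) stop("target macrostate is empty")
  A <- setdiff(seq_len(nrow(Tm)), B)
  m <- numeric(nrow(Tm))
  if (length(A)) {
    M <- diag(length(A)) - Tm[A, A, drop = FALSE]
    rhs <- rep(T@lag, length(A))
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("singular first-passage system (target unreachable)"))
    m[A] <- sol
  }
  m
}

#' Exact macrostate-to-macrostate MFPT table
#'
#' Entry-weighted oracle matching the Monte-Carlo definition: the MFPT
#' from a to b averages the microstate first-passage times
#' \code{\link{mfptExact}} over the stationary flux distribution of
#' entries into a, \eqn{\nu_j \propto \sum_{i \notin a} \pi_i T_{ij}}.
#'
#' @inheritParams mfptExact
#' @return nMacro x nMacro matrix (diagonal 0), time units of the lag.
#' @export
mfptExactTable <- function(T, macro) {
  Tm <- asTMatrix(T)
  pi0 <- stationaryDistribution(Tm)
  nMacro <- macro@nMacro
  out <- matrix(0, nMacro, nMacro)
  for (b in seq_len(nMacro)) {
    m <- mfptExact(T, b, macro)
    for (a in seq_len(nMacro)) {
      if (a == b) next
      inA <- macro@microToMacro == a
      nu <- colSums(Tm[!inA, inA, drop = FALSE] * pi0[!inA])
      if (sum(nu) == 0) nu <- pi0[inA]
      out[a, b] <- sum(nu * m[inA]) / sum(nu)
    }
  }
  out
}
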