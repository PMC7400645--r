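## top right eigenvectors of a symmetrized-count MSM, in the count metric:
## S = (C + C^T)/2, D = diag(rowSums(S)), T = D^-1 S; returns V with
## columns the right eigenvectors of T (D-orthonormal)
msmEigenvectors <- function(S, nEigen) {
  d <- rowSums(S)
  if (any(d <= 0)) stop("empty state in symmetrized counts")
  s <- sqrt(d)
  Ssym <- S / outer(s, s)
  e <- eigen(Ssym, symmetric = TRUE)
  k <- min(nEigen, ncol(S))
  ord <- order(e$values, decreasing = TRUE)[seq_len(k)]
  list(values = e$values[ord],
       vectors = e$vectors[, ord, drop = FALSE] / s)
}

## GMRQ score of trained eigenvectors V on test counts: the generalized
## matrix Rayleigh quotient trace[(V' D V)^-1 (V' S V)]
gmrqScore <- function(V, Ctest) {
  S <- (Ctest + t(Ctest)) / 2
  present <- which(rowSums(S) > 0)
  if (length(present) < nrow(S)) {
    S <- S[present, present, drop = FALSE]
    V <- V[present, , drop = FALSE]
  }
  D <- diag(rowSums(S), nrow(S))
  A <- crossprod(V, D %*% V)
  B <- crossprod(V, S %*% V)
  sum(diag(solve(A, B)))
}

#' GMRQ shuffle-split cross-validation of MSM hyper-parameters
#'
#' For each parameter set (tICA lag, number of tICs, number of k-center
#' clusters, MSM lag) and each of \code{nSplits} iterations, half of the
#' trajectories (at random) train a tICA + k-center + symmetrized-MSM
#' model and the other half score it: the score is the generalized matrix
#' Rayleigh quotient of the model's top \code{nEigen} eigenvectors
#' evaluated on the held-out correlation matrices (sum of the top
#' eigenvalues when train = test).  Higher is better; the population score
#' is bounded above by the sum of the true top eigenvalues (variational
#' principle) and by \code{nEigen}.
#'
#' @param features a \linkS4class{FeatureMatrix} with at least 2
#'   trajectories.
#' @param paramGrid data.frame with any of the columns \code{ticaLag},
#'   \code{nTics}, \code{nClusters}, \code{msmLag} (frames); missing
#'   columns take the defaults 10, 4, 100, 10.
#' @param nSplits shuffle-split iterations (default 50).
#' @param nEigen eigenvalues summed in the score (default 5).
#' @param seed integer seed.
#' @return \code{paramGrid} with columns \code{meanScore}, \code{sdScore},
#'   \code{nValid} appended.
#' @export
gmrqCrossValidate <- function(features, paramGrid, nSplits = 50L,
                              nEigen = 5L, seed = 1L) {
  stopifnot(is(features, "FeatureMatrix"))
  nTraj <- length(features@trajLengths)
  if (nTraj < 2L) stop("need at least 2 trajectories to split")
  defaults <- list(ticaLag = 10L, nTics = 4L, nClusters = 100L,
                   msmLag = 10L)
  for (nm in names(defaults))
    if (is.null(paramGrid[[nm]])) paramGrid[[nm]] <- defaults[[nm]]
  trajFeat <- splitByTrajRows(features)
  scores <- matrix(NA_real_, nrow(paramGrid), nSplits)
  for (it in seq_len(nSplits)) {
    trainIdx <- localSeed(subSeed(seed, it),
                          sample.int(nTraj, max(1L, nTraj %/% 2L)))
    testIdx <- setdiff(seq_len(nTraj), trainIdx)
    for (r in seq_len(nrow(paramGrid))) {
      p <- paramGrid[r, ]
      sc <- tryCatch({
        trainFm <- bindTraj(trajFeat[trainIdx], features@frameInterval)
        tica <- suppressWarnings(
          fitTica(trainFm, lag = p$ticaLag, nComponents = p$nTics))
        proj <- projectData(tica, trainFm)
        km <- kcenterCluster(proj, k = min(p$nClusters, nrow(proj)),
                             seed = subSeed(seed, it * 131L + r),
                             trajLengths = trainFm@trajLengths)
        Ctrain <- countMatrix(km@assignments, nrow(km@centers),
                              lag = p$msmLag)
        V <- msmEigenvectors((Ctrain + t(Ctrain)) / 2, nEigen)$vectors
        testAssign <- lapply(testIdx, function(j) {
          assignToCenters(projectData(tica, trajFeat[[j]]), km@centers)
        })
        Ctest <- countMatrix(testAssign, nrow(km@centers), lag = p$msmLag)
        if (sum(Ctest) == 0) stop("test set too short for msmLag")
        gmrqScore(V, Ctest)
      }, error = function(e) NA_real_)
      scores[r, it] <- sc
    }
  }
  paramGrid$meanScore <- rowMeans(scores, na.rm = TRUE)
  paramGrid$sdScore <- apply(scores, 1L, sd, na.rm = TRUE)
  paramGrid$nValid <- rowSums(!is.na(scores))
  paramGrid
}

## helpers to slice a FeatureMatrix by trajectory
splitByTrajRows <- function(fm) {
  ends <- cumsum(fm@trajLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(starts), function(j)
    fm@values[starts[j]:ends[j], , drop = FALSE])
}

bindTraj <- function(mats, frameInterval) {
  new("FeatureMatrix", values = do.call(rbind, mats),
      frameInterval = frameInterval,
      trajLengths = vapply(mats, nrow, integer(1)))
}
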