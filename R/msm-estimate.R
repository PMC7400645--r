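#' Estimate a transition matrix from state assignments
#'
#' Sliding-window (stride-1) transition counts at the given lag within
#' each trajectory, never across trajectory boundaries.  In
#' \code{"symmetrized"} mode the counts are symmetrized,
#' \eqn{(C + C^T)/2}, before row normalization, which makes the matrix
#' reversible with a real eigenvalue spectrum; \code{"raw"} mode
#' normalizes \eqn{C} directly.  States with an empty count row are
#' dropped with a warning (use \code{\link{pruneStates}} first to keep the
#' model connected).
#'
#' @param assignments list of integer state vectors (e.g.
#'   \code{assignments(model)} of a \linkS4class{MicrostateModel}), or a
#'   single integer vector.
#' @param lag counting lag in frames.
#' @param mode \code{"symmetrized"} (default) or \code{"raw"}.
#' @param nStates total number of states (default: max observed).
#' @param frameInterval time per frame (ns) used to report the lag time.
#' @return A \linkS4class{TransitionMatrix}; attribute \code{"states"} of
#'   the matrix gives the original indices of the retained states.
#' @export
estimateTransitionMatrix <- function(assignments, lag = 1L,
                                     mode = c("symmetrized", "raw"),
                                     nStates = NULL, frameInterval = 1) {
  mode <- match.arg(mode)
  if (!is.list(assignments)) assignments <- list(assignments)
  assignments <- lapply(assignments, as.integer)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(nStates))
    nStates <- max(unlist(assignments, use.names = FALSE))
  C <- countMatrix(assignments, nStates, lag = lag)
  M <- if (mode == "symmetrized") (C + t(C)) / 2 else C
  keep <- which(rowSums(M) > 0)
  if (length(keep) < nStates) {
    warning(nStates - length(keep),
            " state(s) with no outgoing counts dropped")
    M <- M[keep, keep, drop = FALSE]
    C <- C[keep, keep, drop = FALSE]
  }
  Tm <- rowNormalize(M)
  attr(Tm, "states") <- keep
  new("TransitionMatrix", matrix = Tm, lag = lag * frameInterval,
      lagUnit = if (frameInterval == 1) "steps" else "ns",
      counts = C, mode = mode)
}

## eigenvalues sorted by modulus (descending); symmetric solve for
## reversible matrices to keep the spectrum exactly real
sortedEigen <- function(Tm, symmetricHint = TRUE, vectors = FALSE) {
  pi0 <- tryCatch(stationaryDistribution(Tm), error = function(e) NULL)
  if (symmetricHint && !is.null(pi0)) {
    s <- sqrt(pi0)
    S <- (Tm * outer(s, 1 / s)) ; S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values
    ord <- order(abs(vals), decreasing = TRUE)
    out <- list(values = vals[ord])
    if (vectors) out$vectors <- (e$vectors / s)[, ord, drop = FALSE]
    out
  } else {
    e <- eigen(Tm)
    ord <- order(Mod(e$values), decreasing = TRUE)
    out <- list(values = e$values[ord])
    if (vectors) out$vectors <- e$vectors[, ord, drop = FALSE]
    out
  }
}

#' Implied timescales with trajectory bootstrap
#'
#' For each lag, estimates a (symmetrized) transition matrix, takes
#' eigenvalues 2..\code{nK}+1 sorted by modulus, and converts each to a
#' relaxation time \eqn{\tau_k = -\tau / \ln \mu_k(\tau)}.  Eigenvalues
#' outside (0, 1) give an undefined (NA) timescale, flagged rather than
#' fabricated.  Uncertainty comes from bootstrapping whole trajectories
#' with replacement.
#'
#' @param assignments list of integer state trajectories.
#' @param lags integer vector of lags (frames); each must be shorter than
#'   the longest trajectory.
#' @param nK number of timescales (default 5).
#' @param nBoot bootstrap samples over trajectories (default 100).
#' @param seed integer seed.
#' @param frameInterval time per frame (ns).
#' @return data.frame with columns \code{lag} (time units),
#'   \code{k} (2-based index of the eigenvalue), \code{timescale} (point
#'   estimate), \code{bootMean}, \code{bootSd}, \code{undefined}.
#' @export
impliedTimescales <- function(assignments, lags, nK = 5L, nBoot = 100L,
                              seed = 1L, frameInterval = 1) {
  if (!is.list(assignments)) assignments <- list(assignments)
  maxLen <- max(lengths(assignments))
  if (any(lags >= maxLen)) stop("every lag must be below the longest ",
                                "trajectory length")
  nStates <- max(unlist(assignments, use.names = FALSE))
  nK <- min(nK, nStates - 1L)
  tsAtLag <- function(trajs, lag) {
    Tm <- suppressWarnings(
      estimateTransitionMatrix(trajs, lag = lag, nStates = nStates,
                               frameInterval = frameInterval))
    mu <- sortedEigen(Tm@matrix)$values
    mu <- mu[-1L]
    mu <- c(mu, rep(NA_real_, max(0L, nK - length(mu))))[seq_len(nK)]
    ifelse(!is.na(mu) & mu > 0 & mu < 1,
           -lag * frameInterval / log(mu), NA_real_)
  }
  nTraj <- length(assignments)
  rows <- lapply(lags, function(lag) {
    pt <- tsAtLag(assignments, lag)
    boot <- localSeed(subSeed(seed, lag), {
      replicate(nBoot, {
        idx <- sample.int(nTraj, nTraj, replace = TRUE)
        tsAtLag(assignments[idx], lag)
      })
    })
    boot <- matrix(boot, nrow = nK)
    data.frame(lag = lag * frameInterval, k = seq_len(nK) + 1L,
               timescale = pt,
               bootMean = rowMeans(boot, na.rm = TRUE),
               bootSd = apply(boot, 1L, sd, na.rm = TRUE),
               undefined = is.na(pt))
  })
  do.call(rbind, rows)
}

#' Residence-probability validation of a transition matrix
#'
#' Compares, for each requested state, the model residence probability
#' \eqn{(T^n)_{ii}} against the empirical fraction of length-\eqn{n\tau}
#' windows that start in \eqn{i} and are again (or still) in \eqn{i} after
#' \eqn{n} lags, for \eqn{n\tau} up to \code{horizon}.
#'
#' @param assignments list of integer state trajectories (same state
#'   indexing as \code{T}).
#' @param T a \linkS4class{TransitionMatrix} estimated at some lag (in
#'   frames; its \code{lag} slot is interpreted in frames here).
#' @param states states to check (default: all).
#' @param horizon maximum time in frames; must be a multiple of the lag.
#' @return data.frame with columns \code{state}, \code{n}, \code{model},
#'   \code{empirical}, \code{nWindows}; attribute \code{"maxAbsDev"}
#'   carries the maximum absolute model-empirical deviation.
#' @export
residenceProbabilityCheck <- function(assignments, T, states = NULL,
                                      horizon) {
  stopifnot(is(T, "TransitionMatrix"))
  if (!is.list(assignments)) assignments <- list(assignments)
  lag <- as.integer(round(T@lag))
  if (horizon %% lag != 0) stop("horizon must be a multiple of the lag")
  nSteps <- horizon %/% lag
  Tm <- T@matrix
  if (is.null(states)) states <- seq_len(nrow(Tm))
  Tn <- diag(nrow(Tm))
  rows <- list()
  for (n in seq_len(nSteps)) {
    Tn <- Tn %*% Tm
    for (s in states) {
      inS <- lapply(assignments, function(a) a == s)
      num <- 0L; den <- 0L
      for (m in inS) {
        L <- length(m)
        if (L <= n * lag) next
        st <- which(m[seq_len(L - n * lag)])
        den <- den + length(st)
        num <- num + sum(m[st + n * lag])
      }
      if (den == 0L) {
        warning("state ", s, " has no windows at n = ", n, "; skipped")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(state = s, n = n, model = Tn[s, s],
                   empirical = num / den, nWindows = den)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "maxAbsDev") <- max(abs(out$model - out$empirical))
  out
}
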