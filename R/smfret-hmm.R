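#' FRET efficiency from donor/acceptor intensities
#'
#' \eqn{E = I_A / (I_A + I_D)}, with no gamma or background correction
#' (correction hooks are a documented extension point).  Frames with
#' non-positive total intensity are flagged as NA and excluded downstream.
#'
#' @param x a \linkS4class{FretTraceSet} or a single trace data.frame
#'   (columns \code{donor}, \code{acceptor}, or a precomputed
#'   \code{efficiency}).
#' @return For a data.frame, a numeric vector; for a trace set, a list of
#'   numeric vectors (one per trace).
#' @export
computeEfficiency <- function(x) {
  one <- function(tr) {
    if ("efficiency" %in% names(tr)) return(tr$efficiency)
    tot <- tr$donor + tr$acceptor
    e <- tr$acceptor / tot
    e[tot <= 0] <- NA_real_
    e
  }
  if (is(x, "FretTraceSet")) lapply(x@traces, one)
  else if (is.data.frame(x)) one(x)
  else stop("x must be a FretTraceSet or a trace data.frame")
}

#' @rdname accessors
#' @export
setMethod("efficiencies", "FretTraceSet", function(x) computeEfficiency(x))

## pad a list of numeric vectors to an L x N matrix (NA beyond each end)
padTraces <- function(tr) {
  L <- max(lengths(tr))
  vapply(tr, function(v) c(v, rep(NA_real_, L - length(v))), numeric(L))
}

## One Baum-Welch EM run, vectorized across traces.  obs: L x N matrix
## with NA for missing frames.  Returns NULL on empty-state collapse.
baumWelch <- function(obs, K, means0, sds0, maxIter = 200L, tol = 1e-6,
                      sdFloor = 1e-4) {
  L <- nrow(obs); N <- ncol(obs)
  m <- means0; s <- pmax(sds0, sdFloor)
  A <- matrix(0.05 / max(1L, K - 1L), K, K); diag(A) <- if (K > 1L) 0.95 else 1
  p <- rep(1 / K, K)
  miss <- is.na(obs)
  ll <- -Inf
  emis <- function(t) {
    B <- vapply(seq_len(K), function(k)
      dnorm(obs[t, ], m[k], s[k]), numeric(N))
    B <- matrix(B, N, K)
    B[miss[t, ], ] <- 1
    B + 1e-300
  }
  for (iter in seq_len(maxIter)) {
    alpha <- array(0, c(L, N, K)); scal <- matrix(0, L, N)
    B1 <- emis(1L)
    a <- sweep(B1, 2L, p, "*")
    scal[1L, ] <- rowSums(a)
    alpha[1L, , ] <- a / scal[1L, ]
    for (t in 2L:L) {
      a <- (matrix(alpha[t - 1L, , ], N, K) %*% A) * emis(t)
      scal[t, ] <- rowSums(a)
      alpha[t, , ] <- a / scal[t, ]
    }
    newll <- sum(log(scal))
    beta <- array(0, c(L, N, K))
    beta[L, , ] <- 1
    xiSum <- matrix(0, K, K)
    for (t in (L - 1L):1L) {
      Bt1 <- emis(t + 1L)
      bb <- matrix(beta[t + 1L, , ], N, K) * Bt1
      beta[t, , ] <- (bb %*% t(A)) / scal[t + 1L, ]
      ## xi accumulation: sum over traces of alpha_t,i A_ij b_j beta_{t+1,j}
      at <- matrix(alpha[t, , ], N, K)
      xiSum <- xiSum + crossprod(at, bb / scal[t + 1L, ]) * A
    }
    gamma <- alpha * beta          # L x N x K, rows sum to 1
    gm <- matrix(gamma, L * N, K)
    obsv <- as.vector(obs)
    ok <- !is.na(obsv)
    wsum <- colSums(gm[ok, , drop = FALSE])
    if (any(wsum < 1)) return(NULL)   # empty state: caller restarts
    m <- colSums(gm[ok, , drop = FALSE] * obsv[ok]) / wsum
    v <- colSums(gm[ok, , drop = FALSE] *
                   (outer(obsv[ok], m, "-"))^2) / wsum
    s <- pmax(sqrt(v), sdFloor)
    if (K > 1L) A <- rowNormalize(xiSum)
    p <- colMeans(matrix(gamma[1L, , ], N, K))
    if (newll < ll - 1e-8 * max(1, abs(ll)))
      stop("EM log-likelihood decreased (", ll, " -> ", newll,
           "); numerical failure")
    done <- is.finite(ll) && (newll - ll) < tol * max(1, abs(newll))
    ll <- newll
    if (done) break
  }
  list(means = m, sds = s, A = A, p = p, logLik = ll,
       converged = iter < maxIter || done)
}

## Viterbi decoding, vectorized across traces
viterbiDecode <- function(obs, m, s, A, p) {
  L <- nrow(obs); N <- ncol(obs); K <- length(m)
  miss <- is.na(obs)
  logA <- log(A + 1e-300)
  emis <- function(t) {
    B <- vapply(seq_len(K), function(k)
      dnorm(obs[t, ], m[k], s[k], log = TRUE), numeric(N))
    B <- matrix(B, N, K)
    B[miss[t, ], ] <- 0
    B
  }
  delta <- matrix(log(p + 1e-300), N, K, byrow = TRUE) + emis(1L)
  psi <- array(0L, c(L, N, K))
  for (t in 2L:L) {
    best <- matrix(0, N, K); arg <- matrix(0L, N, K)
    for (k in seq_len(K)) {
      cand <- delta + matrix(logA[, k], N, K, byrow = TRUE)
      arg[, k] <- max.col(cand, ties.method = "first")
      best[, k] <- cand[cbind(seq_len(N), arg[, k])]
    }
    delta <- best + emis(t)
    psi[t, , ] <- arg
  }
  paths <- matrix(0L, L, N)
  paths[L, ] <- max.col(delta, ties.method = "first")
  for (t in (L - 1L):1L)
    paths[t, ] <- matrix(psi[t + 1L, , ], N, K)[
      cbind(seq_len(N), paths[t + 1L, ])]
  paths
}

## seeded k-means-style initial emission parameters
hmmInit <- function(values, K, seed) {
  localSeed(seed, {
    if (K == 1L) return(list(means = mean(values), sds = max(sd(values),
                                                             1e-3)))
    km <- suppressWarnings(
      kmeans(values, centers = K, nstart = 3L, iter.max = 50L))
    ord <- order(km$centers)
    sds <- sqrt(km$withinss / pmax(km$size, 1L))[ord]
    list(means = as.numeric(km$centers[ord]),
         sds = pmax(sds, 1e-3))
  })
}

#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' Maximum-likelihood Baum-Welch EM with seeded k-means initialization of
#' the emission parameters; the log-likelihood is checked to be
#' non-decreasing every iteration.  When \code{nStates} is NULL, models
#' with 1..\code{KMax} states are fitted and the minimum-BIC model is
#' returned.  An EM run that empties a state is restarted with a new seed
#' (up to 5 restarts).  Idealized state paths are obtained by Viterbi
#' decoding, and states are relabelled so emission means sort ascending.
#'
#' @param traces a \linkS4class{FretTraceSet} or list of numeric
#'   efficiency vectors.
#' @param nStates fixed state count, or NULL for BIC model selection.
#' @param KMax largest state count tried in model selection (default 6).
#' @param seed integer seed.
#' @param maxIter,tol EM iteration cap and relative convergence tolerance.
#' @return An \linkS4class{HmmFit}.
#' @export
fitHmm <- function(traces, nStates = NULL, KMax = 6L, seed = 1L,
                   maxIter = 200L, tol = 1e-6) {
  tr <- if (is(traces, "FretTraceSet")) computeEfficiency(traces)
        else traces
  obs <- padTraces(tr)
  values <- as.vector(obs); values <- values[!is.na(values)]
  nObs <- length(values)
  fitK <- function(K) {
    if (nObs < 50L * K)
      stop("need at least ", 50L * K, " frames to fit ", K, " states")
    fit <- NULL
    for (attempt in 0:5) {
      init <- hmmInit(values, K, subSeed(seed, 17L * K + attempt))
      fit <- baumWelch(obs, K, init$means, init$sds, maxIter = maxIter,
                       tol = tol)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("EM kept emptying a state after 5 restarts (K = ", K, ")")
    nPar <- (K - 1) + K * (K - 1) + 2 * K
    fit$bic <- -2 * fit$logLik + nPar * log(nObs)
    fit$K <- K
    fit
  }
  fit <- if (!is.null(nStates)) fitK(as.integer(nStates)) else {
    cand <- lapply(seq_len(KMax), function(K)
      tryCatch(fitK(K), error = function(e) NULL))
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) stop("no HMM could be fitted")
    cand[[which.min(vapply(cand, `[[`, numeric(1), "bic"))]]
  }
  ord <- order(fit$means)
  m <- fit$means[ord]; s <- fit$sds[ord]
  A <- fit$A[ord, ord, drop = FALSE]
  p <- fit$p[ord]
  relabel <- match(seq_along(ord), ord)
  pathsM <- viterbiDecode(obs, m, s, A, p)
  paths <- lapply(seq_along(tr), function(j)
    as.integer(pathsM[seq_along(tr[[j]]), j]))
  new("HmmFit", nStates = as.integer(fit$K), means = m, sds = s,
      transition = A, initial = p / sum(p), logLik = fit$logLik,
      bic = fit$bic, paths = paths, converged = isTRUE(fit$converged))
}

#' Fit a 1D Gaussian mixture by EM
#'
#' Seeded k-means initialization, standard EM, component-collapse
#' restarts (up to 5) when a component's sd falls below 1e-6 of the data
#' range.  Components are reported sorted by center descending; weights
#' sum to 1.
#'
#' @param samples numeric vector (>= 20 per component).
#' @param nComponents number of Gaussians (default 4).
#' @param seed integer seed.
#' @param maxIter,tol EM controls.
#' @return data.frame with columns \code{center}, \code{sd}, \code{weight}
#'   (rows sorted by center descending); attributes \code{"logLik"} and
#'   \code{"bic"}.
#' @export
fitGaussianMixture1d <- function(samples, nComponents = 4L, seed = 1L,
                                 maxIter = 500L, tol = 1e-8) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  K <- as.integer(nComponents)
  if (n < 20L * K) stop("need at least ", 20L * K, " samples")
  floorSd <- 1e-6 * diff(range(samples))
  runEM <- function(att) {
    init <- hmmInit(samples, K, subSeed(seed, 29L * K + att))
    m <- if (K == 1L) init$means else init$means
    s <- pmax(if (K == 1L) init$sds else init$sds, floorSd * 10)
    w <- rep(1 / K, K)
    ll <- -Inf
    for (iter in seq_len(maxIter)) {
      dens <- vapply(seq_len(K), function(k)
        w[k] * dnorm(samples, m[k], s[k]), numeric(n))
      dens <- matrix(dens, n, K) + 1e-300
      tot <- rowSums(dens)
      newll <- sum(log(tot))
      r <- dens / tot
      nk <- colSums(r)
      if (any(nk < 1e-8)) return(NULL)
      w <- nk / n
      m <- colSums(r * samples) / nk
      s <- sqrt(colSums(r * (outer(samples, m, "-"))^2) / nk)
      if (any(s < floorSd)) return(NULL)
      if (is.finite(ll) && newll - ll < tol * max(1, abs(newll))) {
        ll <- newll; break
      }
      ll <- newll
    }
    list(m = m, s = s, w = w, ll = ll)
  }
  fit <- NULL
  for (att in 0:5) {
    fit <- runEM(att)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("mixture EM kept collapsing a component after 5 restarts")
  ord <- order(fit$m, decreasing = TRUE)
  out <- data.frame(center = fit$m[ord], sd = fit$s[ord],
                    weight = fit$w[ord])
  nPar <- K * 3 - 1
  attr(out, "logLik") <- fit$ll
  attr(out, "bic") <- -2 * fit$ll + nPar * log(n)
  out
}
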