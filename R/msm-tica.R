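## time-lagged pair views of a FeatureMatrix: rows t and t+lag within each
## trajectory, never across boundaries
lagPairs <- function(fm, lag) {
  ends <- cumsum(fm@trajLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  i0 <- unlist(lapply(seq_along(starts), function(j) {
    if (fm@trajLengths[j] <= lag) integer() else
      seq(starts[j], ends[j] - lag)
  }), use.names = FALSE)
  list(i0 = i0, i1 = i0 + lag)
}

#' Fit a tICA model
#'
#' Solves the generalized eigenproblem of the symmetrized time-lagged
#' covariance matrix against the instantaneous covariance,
#' \eqn{C_\tau v = \lambda C_0 v}.  Both covariances are estimated over
#' the time-lagged pair ensemble (frames t and t+lag pooled), after
#' removing the pooled mean, so the scalar case reduces to the empirical
#' lag-\eqn{\tau} autocorrelation.  A ridge of \code{1e-8 * trace/dim} is
#' added to a near-singular instantaneous covariance, with a warning.
#'
#' @param features a \linkS4class{FeatureMatrix}; every trajectory must be
#'   longer than \code{lag}.
#' @param lag tICA lag in frames.
#' @param nComponents components kept for projection (default: all).
#' @return A \linkS4class{TicaModel}; project with
#'   \code{\link{projectData}}.
#' @export
fitTica <- function(features, lag, nComponents = NULL) {
  stopifnot(is(features, "FeatureMatrix"))
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1 frame")
  if (all(features@trajLengths <= lag))
    stop("every trajectory is shorter than the lag")
  X <- features@values
  p <- lagPairs(features, lag)
  Y0 <- X[p$i0, , drop = FALSE]; Y1 <- X[p$i1, , drop = FALSE]
  mu <- colMeans(rbind(Y0, Y1))
  Y0 <- sweep(Y0, 2L, mu); Y1 <- sweep(Y1, 2L, mu)
  np <- nrow(Y0)
  C0 <- (crossprod(Y0) + crossprod(Y1)) / (2 * np)
  Ct <- (crossprod(Y0, Y1) + crossprod(Y1, Y0)) / (2 * np)
  d <- ncol(X)
  ev0 <- eigen(C0, symmetric = TRUE)
  ridge <- 1e-8 * sum(diag(C0)) / d
  if (min(ev0$values) < ridge) {
    warning("near-singular instantaneous covariance; adding ridge ", ridge)
    C0 <- C0 + diag(ridge, d)
    ev0 <- eigen(C0, symmetric = TRUE)
  }
  W <- ev0$vectors %*% diag(1 / sqrt(ev0$values), d) %*% t(ev0$vectors)
  M <- W %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  comp <- W %*% em$vectors
  if (is.null(nComponents)) nComponents <- d
  nComponents <- min(as.integer(nComponents), d)
  colnames(comp) <- paste0("tIC", seq_len(d))
  new("TicaModel", lag = lag, means = mu, components = comp,
      eigenvalues = em$values, nComponentsKept = nComponents)
}

#' @describeIn fitTica Project frames onto the kept tICs.
#' @param object a fitted \linkS4class{TicaModel}.
#' @param newdata a \linkS4class{FeatureMatrix} or numeric matrix with the
#'   same features.
#' @param ... unused.
#' @export
setMethod("projectData", "TicaModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureMatrix")) newdata@values else as.matrix(newdata)
  if (ncol(X) != length(object@means))
    stop("feature dimension mismatch")
  sweep(X, 2L, object@means) %*%
    object@components[, seq_len(object@nComponentsKept), drop = FALSE]
})
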