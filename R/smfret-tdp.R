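#' Build a transition density plot from an HMM fit
#'
#' Collects the change points of the idealized (Viterbi) paths as
#' (efficiency before, efficiency after) pairs — taking each state's
#' fitted emission mean as its ideal efficiency — and dresses every point
#' with a unit-mass isotropic 2D Gaussian of width \code{sigma} evaluated
#' on the grid, so the density integrates to the number of transitions.
#'
#' @param hmmFit an \linkS4class{HmmFit}.
#' @param grid numeric vector of grid coordinates used for both axes
#'   (default 0..1 in steps of 0.01).
#' @param sigma dressing width in efficiency units (default 0.03).
#' @return A \linkS4class{TransitionDensity}; empty (with a warning) when
#'   the idealized paths contain no transitions.
#' @export
buildTdp <- function(hmmFit, grid = seq(0, 1, by = 0.01), sigma = 0.03) {
  stopifnot(is(hmmFit, "HmmFit"))
  pts <- do.call(rbind, lapply(hmmFit@paths, function(p) {
    if (length(p) < 2L) return(NULL)
    ch <- which(p[-1L] != p[-length(p)])
    if (!length(ch)) return(NULL)
    cbind(hmmFit@means[p[ch]], hmmFit@means[p[ch + 1L]])
  }))
  if (is.null(pts) || nrow(pts) == 0L) {
    warning("idealized paths contain no transitions; TDP is empty")
    return(new("TransitionDensity", points = matrix(numeric(), 0L, 2L),
               x = grid, y = grid,
               density = matrix(0, length(grid), length(grid)),
               sigma = sigma))
  }
  ## aggregate duplicate (before, after) pairs for speed
  key <- paste(pts[, 1L], pts[, 2L])
  agg <- aggregate(list(n = rep(1L, nrow(pts))),
                   by = list(key = key), FUN = sum)
  uniq <- pts[!duplicated(key), , drop = FALSE]
  cnt <- agg$n[match(paste(uniq[, 1L], uniq[, 2L]), agg$key)]
  Gx <- vapply(seq_len(nrow(uniq)), function(i)
    dnorm(grid, uniq[i, 1L], sigma) * cnt[i], numeric(length(grid)))
  Gy <- vapply(seq_len(nrow(uniq)), function(i)
    dnorm(grid, uniq[i, 2L], sigma), numeric(length(grid)))
  dens <- matrix(Gx, length(grid)) %*% t(matrix(Gy, length(grid)))
  new("TransitionDensity", points = pts, x = grid, y = grid,
      density = dens, sigma = sigma)
}

## 8-neighbour local maxima of a matrix, ordered by height
localMaxima2d <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  P <- matrix(-Inf, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- D
  isMax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    isMax <- isMax & (D >= P[2:(nr + 1L) + di, 2:(nc + 1L) + dj])
  }
  idx <- which(isMax & D > 0, arr.ind = TRUE)
  idx[order(D[idx], decreasing = TRUE), , drop = FALSE]
}

#' Fit a 2D Gaussian mixture to a transition density
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' \code{nComponents} isotropic 2D Gaussians to the dressed density,
#' seeded from the largest local maxima of the grid.  When fewer local
#' maxima exist, the fit proceeds with a reduced component count and the
#' result is flagged.
#'
#' @param tdp a \linkS4class{TransitionDensity}.
#' @param nComponents number of Gaussian components (default 6).
#' @param seed integer seed (small jitter on degenerate seeds).
#' @return data.frame with columns \code{cx}, \code{cy}, \code{sigma},
#'   \code{weight}; attribute \code{"reduced"} TRUE when fewer than
#'   \code{nComponents} could be seeded.
#' @export
fitTdpGaussians <- function(tdp, nComponents = 6L, seed = 1L) {
  stopifnot(is(tdp, "TransitionDensity"))
  if (all(tdp@density <= 0)) stop("empty transition density")
  mx <- localMaxima2d(tdp@density)
  nUse <- min(nComponents, nrow(mx))
  reduced <- nUse < nComponents
  if (reduced)
    warning("only ", nrow(mx), " local maxima; fitting ", nUse,
            " components")
  seeds <- mx[seq_len(nUse), , drop = FALSE]
  x <- tdp@x; y <- tdp@y
  D <- tdp@density
  model <- function(par) {
    cx <- par[seq_len(nUse)]
    cy <- par[nUse + seq_len(nUse)]
    lsig <- par[2L * nUse + seq_len(nUse)]
    lw <- par[3L * nUse + seq_len(nUse)]
    M <- matrix(0, length(x), length(y))
    for (c in seq_len(nUse)) {
      M <- M + exp(lw[c]) * (dnorm(x, cx[c], exp(lsig[c])) %o%
                               dnorm(y, cy[c], exp(lsig[c])))
    }
    M
  }
  w0 <- D[seeds] * 2 * pi * tdp@sigma^2
  par0 <- c(x[seeds[, 1L]], y[seeds[, 2L]],
            rep(log(tdp@sigma), nUse), log(pmax(w0, 1e-6)))
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(p) as.vector(D - model(p)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- fit$par
  out <- data.frame(cx = p[seq_len(nUse)],
                    cy = p[nUse + seq_len(nUse)],
                    sigma = exp(p[2L * nUse + seq_len(nUse)]),
                    weight = exp(p[3L * nUse + seq_len(nUse)]))
  attr(out, "reduced") <- reduced
  out
}

#' Derive per-state efficiency thresholds from a TDP fit
#'
#' Pools the fitted component coordinates (both axes, weighted) into 1D
#' state centers by single-linkage agglomerative merging at
#' \code{linkageCutoff}, then sets each state's classification interval
#' to its pooled center plus/minus half of the full width at half height
#' of its pooled Gaussian, \eqn{FWHH = 2\sqrt{2\ln 2}\,\sigma}.
#' Overlapping intervals (wide widths at close centers) are truncated at
#' the midpoints between adjacent centers.
#'
#' @param fit the data.frame returned by \code{\link{fitTdpGaussians}}.
#' @param linkageCutoff 1D merge distance in efficiency units (default
#'   0.05).
#' @return A \linkS4class{StateThresholds}; pooled centers are stored in
#'   the attribute \code{"centers"} of the bounds.
#' @export
deriveThresholds <- function(fit, linkageCutoff = 0.05) {
  vals <- c(fit$cx, fit$cy)
  wts <- rep(pmax(fit$weight, 1e-12), 2L)
  sig <- rep(fit$sigma, 2L)
  if (length(vals) > 1L) {
    cl <- stats::cutree(stats::hclust(dist(vals), method = "single"),
                        h = linkageCutoff)
  } else cl <- 1L
  centers <- vapply(split(seq_along(vals), cl), function(i)
    sum(vals[i] * wts[i]) / sum(wts[i]), numeric(1))
  sigs <- vapply(split(seq_along(vals), cl), function(i)
    sum(sig[i] * wts[i]) / sum(wts[i]), numeric(1))
  ord <- order(centers)
  centers <- centers[ord]; sigs <- sigs[ord]
  half <- sqrt(2 * log(2)) * sigs
  low <- centers - half; high <- centers + half
  if (length(centers) > 1L) {
    mids <- (centers[-1L] + centers[-length(centers)]) / 2
    high[-length(high)] <- pmin(high[-length(high)], mids - 1e-9)
    low[-1L] <- pmax(low[-1L], mids + 1e-9)
  }
  b <- cbind(low = low, high = high)
  attr(b, "centers") <- centers
  new("StateThresholds", bounds = b)
}

#' Per-state populations by threshold analysis
#'
#' Fraction of frames whose efficiency falls in each state's threshold
#' interval, plus the unassigned remainder; fractions and the unassigned
#' share sum to 1.  The default classifies idealized frames (each frame's
#' fitted emission mean); raw mode classifies measured efficiencies.
#'
#' @param x an \linkS4class{HmmFit} (idealized mode) or
#'   \linkS4class{FretTraceSet}/list of efficiency vectors (raw mode).
#' @param thresholds a \linkS4class{StateThresholds}.
#' @param mode \code{"idealized"} (default, requires an HmmFit) or
#'   \code{"raw"}.
#' @return List with \code{populations} (named fraction per state) and
#'   \code{unassigned}.
#' @export
statePopulations <- function(x, thresholds,
                             mode = c("idealized", "raw")) {
  mode <- match.arg(mode)
  stopifnot(is(thresholds, "StateThresholds"))
  e <- if (is(x, "HmmFit")) {
    if (mode == "raw")
      stop("raw mode needs the traces, not the HMM fit")
    unlist(lapply(x@paths, function(p) x@means[p]), use.names = FALSE)
  } else {
    v <- if (is(x, "FretTraceSet")) computeEfficiency(x) else x
    unlist(v, use.names = FALSE)
  }
  e <- e[is.finite(e)]
  b <- thresholds@bounds
  n <- length(e)
  frac <- vapply(seq_len(nrow(b)), function(i)
    sum(e >= b[i, 1L] & e <= b[i, 2L]) / n, numeric(1))
  names(frac) <- paste0("E", seq_len(nrow(b)))
  list(populations = frac, unassigned = 1 - sum(frac))
}
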