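#' Multi-well 2D landscape specification
#'
#' A free-energy surface defined as minus the log of a Gaussian mixture,
#' \eqn{V(x) = -k_BT \log \sum_i w_i N(x; c_i, s_i^2 I)} with
#' \eqn{w_i = e^{d_i}} for well depth \eqn{d_i} (kT).  The Boltzmann
#' density is then exactly the mixture, so the long-run occupancy of well
#' \eqn{i} is the normalized weight \eqn{w_i/\sum w} when widths are equal
#' — which gives closed-form occupancy oracles for testing.
#'
#' @param wellCenters k x 2 matrix of well centers (tIC-like units).
#' @param wellDepths depths in kT (deeper = more populated).
#' @param wellWidths per-well Gaussian width (recycled).
#' @param temperatureKT thermal energy (kT units; the potential scales with
#'   it, so it sets the noise amplitude).
#' @param dt integration time step.
#' @param friction friction coefficient (1/time).
#' @return A validated list of class \code{"LandscapeSpec"}.
#' @export
landscapeSpec <- function(wellCenters, wellDepths = NULL, wellWidths = 0.5,
                          temperatureKT = 1, dt = 0.02, friction = 1) {
  wellCenters <- as.matrix(wellCenters)
  k <- nrow(wellCenters)
  if (k < 1L || ncol(wellCenters) != 2L)
    stop("wellCenters must be a k x 2 matrix with k >= 1")
  if (is.null(wellDepths)) wellDepths <- rep(1, k)
  if (length(wellDepths) != k) stop("one depth per well required")
  wellWidths <- rep_len(wellWidths, k)
  if (any(wellWidths <= 0)) stop("widths must be > 0")
  stopifnotScalar(dt, "dt", positive = TRUE)
  stopifnotScalar(friction, "friction", positive = TRUE)
  stopifnotScalar(temperatureKT, "temperatureKT")
  if (temperatureKT < 0) stop("temperatureKT must be >= 0")
  structure(list(wellCenters = wellCenters, wellDepths = wellDepths,
                 wellWidths = wellWidths, temperatureKT = temperatureKT,
                 dt = dt, friction = friction),
            class = "LandscapeSpec")
}

#' Default eight-well landscape
#'
#' Wells laid out on the (ligand position in \{small, interface, large\}) x
#' (domain opening in \{closed, semi, open\}) grid minus the unpopulated
#' interface-open cell, mirroring the topology of an eight-macrostate
#' two-domain binding network.  Depths are set from the fixture macrostate
#' populations via \eqn{d_i = \ln p_i} (up to a constant), so well
#' occupancies equal those populations.
#'
#' @param populations stationary populations for the 8 wells (default: the
#'   \code{\link{fixtureNetworkFig2}} populations, in the state order
#'   S1, S2, S3, S4, S5, S6, S1', S4').
#' @param spacing grid spacing between adjacent wells.
#' @param width common well width.
#' @inheritParams landscapeSpec
#' @return A \code{"LandscapeSpec"} whose rows carry the state names.
#' @export
defaultLandscapeSpec <- function(populations = NULL, spacing = 2,
                                 width = 0.5, temperatureKT = 1,
                                 dt = 0.02, friction = 1) {
  if (is.null(populations)) populations <- fixtureNetworkFig2()$macroPopulations
  stopifnot(length(populations) == 8L)
  ## x: ligand position (small -1, interface 0, large +1)
  ## y: opening (closed -1, semi 0, open +1); interface-open cell absent
  grid <- rbind(
    S1  = c(-1, -1), S2  = c(-1,  1), S3  = c(-1, 0),
    S4  = c( 1,  0), S5  = c( 1,  1), S6  = c( 1, -1),
    S1p = c( 0, -1), S4p = c( 0,  0))
  landscapeSpec(grid * spacing, wellDepths = log(populations),
                wellWidths = width, temperatureKT = temperatureKT,
                dt = dt, friction = friction)
}

## mixture responsibilities and force -grad V at positions x (n x 2)
landscapeForce <- function(spec, x) {
  k <- nrow(spec$wellCenters)
  logphi <- vapply(seq_len(k), function(i) {
    d2 <- (x[, 1L] - spec$wellCenters[i, 1L])^2 +
          (x[, 2L] - spec$wellCenters[i, 2L])^2
    spec$wellDepths[i] - 2 * log(spec$wellWidths[i]) -
      d2 / (2 * spec$wellWidths[i]^2)
  }, numeric(nrow(x)))
  logphi <- matrix(logphi, nrow = nrow(x))
  m <- apply(logphi, 1L, max)
  r <- exp(logphi - m)
  r <- r / rowSums(r)
  fx <- numeric(nrow(x)); fy <- numeric(nrow(x))
  for (i in seq_len(k)) {
    s2 <- spec$wellWidths[i]^2
    fx <- fx - r[, i] * (x[, 1L] - spec$wellCenters[i, 1L]) / s2
    fy <- fy - r[, i] * (x[, 2L] - spec$wellCenters[i, 2L]) / s2
  }
  ## V = -kT log(mixture)  =>  -grad V = kT * sum_i r_i (c_i - x)/s_i^2
  cbind(fx, fy) * spec$temperatureKT
}

#' Overdamped Langevin (Brownian dynamics) sampling of a landscape
#'
#' Euler-Maruyama integration of
#' \eqn{dx = -\nabla V(x)\,dt/\gamma + \sqrt{2 k_BT\,dt/\gamma}\,\eta}.
#' Starting positions are drawn from the wells in proportion to their
#' Boltzmann weights (or supplied).  Emits a two-column
#' \linkS4class{FeatureMatrix} of the sampled coordinates.
#'
#' @param spec a \code{\link{landscapeSpec}}.
#' @param nTraj number of independent trajectories.
#' @param nSteps steps per trajectory.
#' @param seed integer seed.
#' @param start optional nTraj x 2 matrix of starting points.
#' @return A \linkS4class{FeatureMatrix} (columns \code{tic_like_1},
#'   \code{tic_like_2}); frame interval is \code{dt}.
#' @export
simulateLandscape <- function(spec, nTraj, nSteps, seed = 1L, start = NULL) {
  stopifnot(inherits(spec, "LandscapeSpec"))
  if (nSteps < 1L) stop("nSteps must be >= 1")
  noiseAmp <- sqrt(2 * spec$temperatureKT * spec$dt / spec$friction)
  if (noiseAmp > min(spec$wellWidths))
    warning("dt too large for stability: per-step displacement exceeds ",
            "the narrowest well width")
  localSeed(seed, {
    if (is.null(start)) {
      w <- exp(spec$wellDepths - max(spec$wellDepths))
      idx <- sample.int(nrow(spec$wellCenters), nTraj, replace = TRUE,
                        prob = w / sum(w))
      start <- spec$wellCenters[idx, , drop = FALSE] +
        matrix(rnorm(2L * nTraj, sd = min(spec$wellWidths) / 2), ncol = 2L)
    }
    x <- start
    out <- array(NA_real_, c(nSteps, nTraj, 2L))
    out[1L, , ] <- x
    if (nSteps > 1L) for (t in 2L:nSteps) {
      f <- landscapeForce(spec, x)
      x <- x + f * (spec$dt / spec$friction) +
        matrix(rnorm(2L * nTraj, sd = noiseAmp), ncol = 2L)
      out[t, , ] <- x
    }
    vals <- do.call(rbind, lapply(seq_len(nTraj), function(j) out[, j, ]))
    colnames(vals) <- c("tic_like_1", "tic_like_2")
    new("FeatureMatrix", values = vals, frameInterval = spec$dt,
        trajLengths = rep(as.integer(nSteps), nTraj))
  })
}

#' Nearest-well labels for landscape points
#'
#' Ground-truth basin assignment: index of the nearest well center.
#'
#' @param points n x 2 matrix (or a \linkS4class{FeatureMatrix}).
#' @param spec the \code{\link{landscapeSpec}} that generated them.
#' @return Integer vector of well indices.
#' @export
nearestWell <- function(points, spec) {
  if (is(points, "FeatureMatrix")) points <- featureValues(points)
  d <- crossDist(points, spec$wellCenters)
  max.col(-d, ties.method = "first")
}
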