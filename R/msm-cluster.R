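## nearest-center assignment, chunked to bound memory
assignToCenters <- function(points, centers, chunk = 20000L) {
  n <- nrow(points)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- crossDist(points[s:e, , drop = FALSE], centers)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

splitByTraj <- function(x, trajLengths) {
  ends <- cumsum(trajLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(starts), function(j) x[starts[j]:ends[j]])
}

#' Greedy k-center clustering of projected frames
#'
#' Max-min (Gonzalez) k-center: the first center is the first point of a
#' seeded random shuffle; every subsequent center is the point farthest
#' from all existing centers (ties to the lowest index).  Assignment is to
#' the nearest center in Euclidean distance.  The greedy covering radius
#' is within a factor 2 of the optimal k-center radius.
#'
#' @param points numeric matrix of projected frames (frames x dims), or a
#'   \linkS4class{FeatureMatrix}.
#' @param k number of clusters (<= number of points).
#' @param seed integer seed for the shuffle (determines the first center).
#' @param trajLengths partition of the rows into trajectories (default:
#'   taken from \code{points} when it is a \linkS4class{FeatureMatrix},
#'   else a single trajectory).
#' @param firstCenter optional row index of the first center, overriding
#'   the seeded choice.
#' @return A \linkS4class{MicrostateModel}; the covering radius is stored
#'   as attribute \code{"radius"} of the centers.
#' @export
kcenterCluster <- function(points, k, seed = 1L, trajLengths = NULL,
                           firstCenter = NULL) {
  if (is(points, "FeatureMatrix")) {
    if (is.null(trajLengths)) trajLengths <- points@trajLengths
    points <- points@values
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k must not exceed the number of points")
  if (is.null(trajLengths)) trajLengths <- n
  first <- if (!is.null(firstCenter)) as.integer(firstCenter)
           else localSeed(seed, sample.int(n, 1L))
  centerIdx <- integer(k)
  centerIdx[1L] <- first
  minD <- rowNorms(sweep(points, 2L, points[first, ]))
  if (k > 1L) for (j in 2L:k) {
    nxt <- which.max(minD)
    centerIdx[j] <- nxt
    dNew <- rowNorms(sweep(points, 2L, points[nxt, ]))
    minD <- pmin(minD, dNew)
  }
  centers <- points[centerIdx, , drop = FALSE]
  a <- assignToCenters(points, centers)
  counts <- tabulate(a, nbins = k)
  attr(centers, "radius") <- max(minD)
  new("MicrostateModel", centers = centers,
      assignments = splitByTraj(a, as.integer(trajLengths)),
      counts = as.integer(counts),
      activeStateMap = seq_len(k))
}

## lag-1 transition count matrix over a list of integer trajectories
countMatrix <- function(assignLists, nStates, lag = 1L) {
  C <- matrix(0, nStates, nStates)
  for (a in assignLists) {
    if (length(a) <= lag) next
    i <- a[seq_len(length(a) - lag)]
    j <- a[seq_len(length(a) - lag) + lag]
    tab <- tabulate((i - 1L) * nStates + j, nbins = nStates * nStates)
    C <- C + matrix(tab, nStates, nStates, byrow = TRUE)
  }
  C
}

#' Prune sparsely populated microstates
#'
#' Removes states with fewer than \code{minCount} frames, reassigns their
#' frames to the nearest retained center, then restricts the model to the
#' largest strongly connected component of the lag-1 transition count
#' graph (propagating a transition matrix requires irreducibility), again
#' reassigning any frames that fall outside it.
#'
#' @param model a \linkS4class{MicrostateModel}.
#' @param minCount minimum frames per retained state (default 15).
#' @return A relabelled \linkS4class{MicrostateModel} whose
#'   \code{activeStateMap} maps original state indices to new ones (NA
#'   where pruned).
#' @export
pruneStates <- function(model, minCount = 15L) {
  stopifnot(is(model, "MicrostateModel"))
  keep <- which(model@counts >= minCount)
  if (!length(keep)) stop("all states pruned; lower minCount")
  reassign <- function(keepIdx) {
    map <- rep(NA_integer_, nrow(model@centers))
    map[keepIdx] <- seq_along(keepIdx)
    centers <- model@centers[keepIdx, , drop = FALSE]
    lapply(model@assignments, function(a) {
      bad <- is.na(map[a])
      out <- map[a]
      if (any(bad)) {
        ## recover original coordinates of orphaned frames via their old
        ## center (frames themselves are no longer available here)
        out[bad] <- assignToCenters(
          model@centers[a[bad], , drop = FALSE], centers)
      }
      out
    })
  }
  newAssign <- reassign(keep)
  k <- length(keep)
  C <- countMatrix(newAssign, k)
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- vapply(seq_len(comp$no), function(cc) {
    sum(tabulate(unlist(newAssign, use.names = FALSE), nbins = k)[
      comp$membership == cc])
  }, numeric(1))
  big <- which.max(sizes)
  inScc <- which(comp$membership == big)
  if (length(inScc) < k) {
    keep <- keep[inScc]
    newAssign <- reassign(keep)
  }
  map <- rep(NA_integer_, nrow(model@centers))
  map[keep] <- seq_along(keep)
  counts <- tabulate(unlist(newAssign, use.names = FALSE),
                     nbins = length(keep))
  new("MicrostateModel",
      centers = model@centers[keep, , drop = FALSE],
      assignments = newAssign, counts = as.integer(counts),
      activeStateMap = map)
}
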