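#' @importFrom stats rnorm runif sd setNames dist aggregate approx dnorm
#'   kmeans optimize uniroot var quantile
#' @importFrom utils head tail read.csv write.csv
NULL

## Run expr with a local RNG state seeded from `seed`, restoring the caller's
## stream afterwards.  All stochastic operations in the package funnel
## through this so that (spec, seed) -> output is a pure function.
localSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single number", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

## derive a distinct 31-bit sub-seed, used where one call seeds several
## independent stochastic stages
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k) * 7919) %%
               2147483629)
}

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

isRowStochastic <- function(m, tol = 1e-9) {
  is.matrix(m) && nrow(m) == ncol(m) && all(m >= -tol) &&
    all(abs(rowSums(m) - 1) < tol)
}

rowNormalize <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("cannot row-normalize: empty row", call. = FALSE)
  sweep(m, 1L, rs, "/")
}

## Euclidean norm of rows
rowNorms <- function(m) sqrt(rowSums(m * m))

## pairwise Euclidean distances between rows of a and rows of b
crossDist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
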