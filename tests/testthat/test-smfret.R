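test_that("efficiency computation is ratiometric with flagged dropouts", {
  tr <- data.frame(donor = c(100, 0, 300, 0), acceptor = c(100, 50, 100, 0))
  e <- computeEfficiency(tr)
  expect_equal(e[1:3], c(0.5, 1.0, 0.25))
  expect_true(is.na(e[4]))

  ## precomputed efficiencies pass through untouched
  tr2 <- data.frame(efficiency = c(0.1, 0.9))
  expect_equal(computeEfficiency(tr2), c(0.1, 0.9))
})

test_that("the HMM fit recovers well-separated emission states", {
  ## near-noiseless one-state traces: exact mean, sd at the floor
  sp1 <- fretGeneratorSpec(0.4, emissionSds = 1e-6,
                           chainMatrix = matrix(1, 1, 1),
                           traceLength = 100, nTraces = 3, seed = 1)
  h1 <- fitHmm(generateFretTraces(sp1), nStates = 1, seed = 1)
  expect_equal(emissionMeans(h1), 0.4, tolerance = 1e-4)

  ## two well-separated states: means within 0.02, paths match truth
  A2 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  sp2 <- fretGeneratorSpec(c(0.2, 0.8), emissionSds = 0.05,
                           chainMatrix = A2, traceLength = 500,
                           nTraces = 10, seed = 2)
  tr2 <- generateFretTraces(sp2)
  h2 <- fitHmm(tr2, nStates = 2, seed = 3)
  expect_true(h2@converged)
  expect_lt(max(abs(emissionMeans(h2) - c(0.2, 0.8))), 0.02)
  acc <- mean(unlist(idealizedPaths(h2)) == unlist(statePaths(tr2)))
  expect_gt(acc, 0.98)

  ## idealized-path transition frequencies converge to the chain
  paths <- idealizedPaths(h2)
  cnt <- matrix(0, 2, 2)
  for (p in paths)
    for (i in 1:2)
      cnt[i, ] <- cnt[i, ] + tabulate(p[which(p[-length(p)] == i) + 1L], 2)
  empir <- cnt / rowSums(cnt)
  se <- sqrt(A2 * (1 - A2) / rowSums(cnt))
  expect_true(all(abs(empir - A2) < 4 * se + 0.01))

  ## BIC model selection finds the four-state fixture and its means
  sp4 <- fixtureSmfretFig6(traceLength = 400, nTraces = 30, seed = 4)
  h4 <- fitHmm(generateFretTraces(sp4), KMax = 6, seed = 5)
  expect_equal(h4@nStates, 4L)
  expect_lt(max(abs(emissionMeans(h4) - sp4$emissionMeans)), 0.03)

  ## too little data for the requested state count errors
  expect_error(fitHmm(list(rnorm(40, 0.5, 0.01)), nStates = 4, seed = 1),
               "at least")
})

test_that("the transition density plot integrates to the transition count
          and has no diagonal mass", {
  sp <- fretGeneratorSpec(c(0.2, 0.8),
                          emissionSds = 0.04,
                          chainMatrix = matrix(c(0.9, 0.1, 0.1, 0.9),
                                               2, 2),
                          traceLength = 300, nTraces = 5, seed = 6)
  h <- fitHmm(generateFretTraces(sp), nStates = 2, seed = 7)
  tdp <- buildTdp(h)
  nTrans <- sum(vapply(idealizedPaths(h), function(p)
    sum(p[-1] != p[-length(p)]), numeric(1)))
  expect_equal(nrow(tdp@points), nTrans)
  cell <- (tdp@x[2] - tdp@x[1])^2
  expect_equal(sum(tdp@density) * cell, nTrans, tolerance = 0.01)
  ## idealized paths never self-transition: all mass off-diagonal
  expect_true(all(abs(tdp@points[, 1] - tdp@points[, 2]) > 0.1))

  ## a single transition integrates to one
  h1 <- h; h1@paths <- list(c(1L, 1L, 2L, 2L))
  tdp1 <- buildTdp(h1)
  expect_equal(sum(tdp1@density) * cell, 1, tolerance = 0.01)

  ## no transitions: empty TDP with a warning
  h0 <- h; h0@paths <- list(rep(1L, 10))
  expect_warning(tdp0 <- buildTdp(h0), "no transitions")
  expect_equal(nrow(tdp0@points), 0L)
})

test_that("TDP Gaussian fitting and FWHH thresholds recover the state
          structure", {
  sp <- fixtureSmfretFig6(traceLength = 400, nTraces = 40, seed = 8)
  h <- fitHmm(generateFretTraces(sp), nStates = 4, seed = 9)
  tdp <- buildTdp(h)
  fit <- fitTdpGaussians(tdp, nComponents = 6, seed = 10)
  expect_equal(nrow(fit), 6L)
  ## every fitted center coordinate sits near one of the 4 state means
  nearest <- vapply(c(fit$cx, fit$cy), function(v)
    min(abs(v - sp$emissionMeans)), numeric(1))
  expect_lt(max(nearest), 0.02)

  thr <- deriveThresholds(fit)
  b <- thresholdBounds(thr)
  expect_equal(nrow(b), 4L)
  centers <- attr(b, "centers")
  expect_lt(max(abs(centers - sp$emissionMeans)), 0.02)
  ## intervals are disjoint and ordered
  expect_true(all(diff(as.vector(t(b))) > 0))

  ## closed-form width: center +/- sqrt(2 ln 2) sigma for a hand-made fit
  hand <- data.frame(cx = c(0.2, 0.6), cy = c(0.6, 0.2),
                     sigma = 0.05, weight = 1)
  bh <- thresholdBounds(deriveThresholds(hand))
  expect_equal(unname(bh[, 2] - bh[, 1]),
               rep(2 * sqrt(2 * log(2)) * 0.05, 2), tolerance = 1e-12)
})

test_that("threshold populations measure interval occupancy", {
  ## intervals transcribed from the reference threshold analysis
  b <- rbind(c(0.080, 0.250), c(0.255, 0.415), c(0.435, 0.625),
             c(0.630, 0.790))
  thr <- new("StateThresholds", bounds = b)

  ## all frames at 0.5: everything in E3
  p1 <- statePopulations(list(rep(0.5, 100)), thr, mode = "raw")
  expect_equal(unname(p1$populations), c(0, 0, 1, 0))

  ## uniform frames on [0, 1]: fractions equal the interval lengths
  ## (0.170, 0.160, 0.190, 0.160)
  u <- seq(0, 1, length.out = 200001)
  p2 <- statePopulations(list(u), thr, mode = "raw")
  expect_equal(unname(p2$populations), c(0.170, 0.160, 0.190, 0.160),
               tolerance = 1e-4)
  expect_equal(sum(p2$populations) + p2$unassigned, 1, tolerance = 1e-12)
})

test_that("the full trace-to-populations pipeline recovers the
          generating occupancies", {
  spec <- fixtureSmfretFig6(traceLength = 500, nTraces = 50, seed = 11)
  traces <- generateFretTraces(spec)
  h <- fitHmm(traces, KMax = 5, seed = 12)
  expect_equal(h@nStates, 4L)
  tdp <- buildTdp(h)
  thr <- deriveThresholds(fitTdpGaussians(tdp, seed = 13))
  pops <- statePopulations(h, thr)$populations
  ## ground truth occupancy of the hidden paths, with its SE over traces
  for (k in 1:4) {
    per <- vapply(statePaths(traces), function(p) mean(p == k),
                  numeric(1))
    se <- sd(per) / sqrt(length(per))
    expect_lt(abs(pops[k] - mean(per)), 3 * se + 0.01)
  }
})

test_that("1D Gaussian mixture EM recovers components and mclust agrees", {
  set.seed(20)
  truthW <- c(0.21, 0.46, 0.22, 0.11)
  truthC <- c(4.7, 3.9, 3.6, 3.4)
  n <- 6000
  comp <- sample.int(4, n, replace = TRUE, prob = truthW)
  x <- rnorm(n, truthC[comp], 0.05)
  fit <- fitGaussianMixture1d(x, 4, seed = 21)
  expect_equal(sum(fit$weight), 1, tolerance = 1e-9)
  ## sorted by center descending
  expect_true(all(diff(fit$center) < 0))
  ord <- order(truthC, decreasing = TRUE)
  expect_lt(max(abs(fit$center - truthC[ord])), 0.05)
  seW <- sqrt(truthW[ord] * (1 - truthW[ord]) / n)
  expect_true(all(abs(fit$weight - truthW[ord]) < 3 * seW + 0.02))

  ## independent oracle: mclust finds the same components
  if (requireNamespace("mclust", quietly = TRUE)) {
    z0 <- mclust::unmap(kmeans(x, 4, nstart = 5)$cluster)
    mc <- mclust::meV(data = x, z = z0)
    expect_lt(max(abs(sort(as.numeric(mc$parameters$mean)) -
                        sort(fit$center))), 0.02)
  }

  ## single Gaussian data: BIC prefers one component
  y <- rnorm(2000, 0.5, 0.1)
  f1 <- fitGaussianMixture1d(y, 1, seed = 22)
  f2 <- fitGaussianMixture1d(y, 2, seed = 22)
  expect_lt(attr(f1, "bic"), attr(f2, "bic"))

  expect_error(fitGaussianMixture1d(rnorm(30), 4, seed = 1), "at least")
})
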