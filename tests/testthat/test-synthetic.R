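test_that("network matrices are row-stochastic, reversible and hit the
          requested macrostate populations", {
  ## symmetric 2-state case: equal populations give a doubly stochastic
  ## matrix
  sp2 <- kineticNetworkSpec(c(0.5, 0.5), nMicroPerMacro = 1L,
                            interRateMatrix = matrix(0.1, 2, 2))
  T2 <- buildNetworkMatrix(sp2, seed = 1)
  expect_equal(colSums(transitionMatrix(T2)), c(1, 1), tolerance = 1e-12)

  ## unequal populations: stationary vector of the emitted matrix
  ## (eigendecomposition oracle) matches the spec
  sp <- kineticNetworkSpec(c(2 / 3, 1 / 3), nMicroPerMacro = 1L,
                           interRateMatrix = matrix(0.1, 2, 2))
  Tm <- transitionMatrix(buildNetworkMatrix(sp, seed = 1))
  ev <- eigen(t(Tm))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  expect_equal(v / sum(v), c(2 / 3, 1 / 3), tolerance = 1e-10)

  ## multi-microstate case: rows sum to 1, detailed balance holds, and
  ## aggregated stationary mass matches the macrostate populations
  for (seed in 1:3) {
    spec <- fixtureNetworkFig2()
    To <- buildNetworkMatrix(spec, seed = seed)
    M <- transitionMatrix(To)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    pi0 <- attr(M, "stationary")
    expect_lt(max(abs(pi0 * M - t(pi0 * M))), 1e-10)
    agg <- tapply(pi0, attr(M, "microToMacro"), sum)
    expect_equal(as.numeric(agg), spec$macroPopulations,
                 tolerance = 1e-10)
  }

  expect_error(kineticNetworkSpec(c(0.6, 0.3)), "sum to 1")
})

test_that("discrete trajectory sampling reproduces the stationary law and
          is bit-identical under a fixed seed", {
  ## absorbing identity matrix
  Tid <- new("TransitionMatrix", matrix = diag(3), lag = 1)
  tr <- sampleDiscreteTrajectories(Tid, 4, 50, seed = 1, start = 2L)
  expect_true(all(vapply(tr, function(x) all(x == 2L), logical(1))))

  ## occupancy matches the stationary eigenvector within 3 SE
  T2 <- twoStateMatrix(0.1, 0.2)
  tr <- sampleDiscreteTrajectories(T2, 100, 10000, seed = 7)
  occ0 <- vapply(tr, function(x) mean(x == 1L), numeric(1))
  se <- sd(occ0) / sqrt(length(occ0))
  expect_lt(abs(mean(occ0) - 2 / 3), 3 * se)

  ## determinism
  a <- sampleDiscreteTrajectories(T2, 5, 100, seed = 42)
  b <- sampleDiscreteTrajectories(T2, 5, 100, seed = 42)
  expect_identical(a, b)
  expect_error(sampleDiscreteTrajectories(T2, 2, 0, seed = 1), "length")
})

test_that("landscape simulation reaches Boltzmann well occupancies", {
  ## vanishing temperature: trajectory stays within one well width
  spec0 <- landscapeSpec(rbind(c(0, 0), c(4, 0)), wellDepths = c(1, 1),
                         wellWidths = 0.5, temperatureKT = 1e-8)
  fm <- simulateLandscape(spec0, 1, 500, seed = 1,
                          start = matrix(c(0, 0), 1))
  expect_lt(max(rowSums(featureValues(fm)^2)), 0.5^2)

  ## two equal wells close enough to exchange: 50/50 within 3 SE over
  ## trajectories
  spec <- landscapeSpec(rbind(c(-1, 0), c(1, 0)), wellDepths = c(1, 1),
                        wellWidths = 0.5)
  fm <- simulateLandscape(spec, 30, 3000, seed = 2)
  w <- nearestWell(fm, spec)
  per <- vapply(split(w, rep(1:30, each = 3000)), function(x)
    mean(x == 1L), numeric(1))
  expect_lt(abs(mean(per) - 0.5), 3 * sd(per) / sqrt(30))

  ## 1 kT depth difference: occupancy fraction matches grid integration
  ## of the Boltzmann density (ratio e^1 for well-separated wells)
  spec1 <- landscapeSpec(rbind(c(-1, 0), c(1, 0)), wellDepths = c(2, 1),
                         wellWidths = 0.5)
  gx <- seq(-3.5, 3.5, by = 0.02)
  gr <- as.matrix(expand.grid(gx, gx))
  lw <- function(i) spec1$wellDepths[i] -
    ((gr[, 1] - spec1$wellCenters[i, 1])^2 +
       (gr[, 2] - spec1$wellCenters[i, 2])^2) / (2 * 0.5^2)
  dens <- exp(lw(1)) + exp(lw(2))
  pOracle <- sum(dens[gr[, 1] < 0]) / sum(dens)
  ## e^1 is the separated-well limit; these wells overlap slightly
  expect_equal(pOracle / (1 - pOracle), exp(1), tolerance = 0.1)
  fm1 <- simulateLandscape(spec1, 30, 4000, seed = 3)
  w1 <- nearestWell(fm1, spec1)
  per1 <- vapply(split(w1, rep(1:30, each = 4000)), function(x)
    mean(x == 1L), numeric(1))
  expect_lt(abs(mean(per1) - pOracle), 3 * sd(per1) / sqrt(30))

  ## unstable time step warns
  expect_warning(
    simulateLandscape(landscapeSpec(rbind(c(0, 0)), wellWidths = 0.1,
                                    dt = 0.5),
                      1, 10, seed = 1), "dt too large")
})

test_that("pseudo-structures realize the order-parameter targets", {
  geo0 <- defaultGeometryConfig(jitter = 0)
  ens <- buildPseudoStructures(c("S1", "S5", "S1p"), geo0, seed = 1)
  expect_equal(calcProbeDistance(ens), c(35.0, 46.1, 35.5),
               tolerance = 1e-9)
  expect_equal(calcLigandDisplacement(ens), c(-8, 8, 0),
               tolerance = 1e-7)
  expect_equal(calcPocketRearrangement(ens), c(4, -3, 4),
               tolerance = 1e-9)

  ## zero ligand displacement = equidistant from mirror-symmetric domains
  lig <- ens@frames[[3]][ens@atomGroups$ligand_heavy, ]
  probe <- ens@frames[[3]][ens@atomGroups$probe_pair, ]
  expect_equal(mean(lig[, 1]), mean(probe[, 1]), tolerance = 1e-7)

  ## with jitter, per-state means recover targets within jitter/sqrt(n)
  geo <- defaultGeometryConfig(jitter = 0.3)
  n <- 150
  ens2 <- buildPseudoStructures(rep(c("S2", "S6"), each = n), geo,
                                seed = 2)
  pd <- calcProbeDistance(ens2)
  tol <- 5 * 0.3 * sqrt(2) / sqrt(n)  # probe distance mixes two atoms
  expect_lt(abs(mean(pd[1:n]) - 43.1), tol)
  expect_lt(abs(mean(pd[(n + 1):(2 * n)]) - 35.5), tol)

  ## infeasible geometry errors
  expect_error(geometryConfig(list(X = list(prob = 1)), jitter = 0),
               "needs probe")
  expect_error(geometryConfig(list(
    X = list(probe = -3, ligandDd = 0, pocketDd = 0,
             hbond = rep(3, 4)))), "must be > 0")
})

test_that("synthetic FRET traces follow the hidden chain and emission
          model", {
  ## near-degenerate single state: constant trace at the mean
  sp1 <- fretGeneratorSpec(0.5, emissionSds = 1e-9,
                           chainMatrix = matrix(1, 1, 1),
                           traceLength = 50, nTraces = 2, seed = 1)
  tr1 <- generateFretTraces(sp1)
  expect_equal(tr1@traces[[1]]$efficiency, rep(0.5, 50),
               tolerance = 1e-6)

  ## four-state fixture: occupancies match the chain stationary vector
  ## (eigendecomposition oracle) within 3 SE over traces
  spec <- fixtureSmfretFig6(traceLength = 2000, nTraces = 60, seed = 5)
  tr <- generateFretTraces(spec)
  ev <- eigen(t(spec$chainMatrix))
  pi0 <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi0 <- pi0 / sum(pi0)
  for (k in 1:4) {
    per <- vapply(tr@statePaths, function(p) mean(p == k), numeric(1))
    expect_lt(abs(mean(per) - pi0[k]), 3 * sd(per) / sqrt(length(per)))
  }
  ## hidden-path transition frequencies converge to the chain matrix
  trans <- matrix(0, 4, 4)
  for (p in tr@statePaths)
    for (i in 1:4) {
      from <- which(p[-length(p)] == i)
      trans[i, ] <- trans[i, ] + tabulate(p[from + 1L], 4)
    }
  empir <- trans / rowSums(trans)
  se <- sqrt(spec$chainMatrix * (1 - spec$chainMatrix) /
               rowSums(trans))
  ## simultaneous bound over the 16 cells at the same confidence as a
  ## single 3-SE check (Sidak correction of the per-cell quantile)
  zStar <- qnorm(1 - (2 * pnorm(-3)) / 2 / 16)
  expect_true(all(abs(empir - spec$chainMatrix) <= zStar * se + 1e-12))

  ## clipping and determinism
  expect_true(all(unlist(computeEfficiency(tr)) >= -0.2))
  expect_true(all(unlist(computeEfficiency(tr)) <= 1.2))
  expect_identical(generateFretTraces(spec), tr)
})

test_that("energy tables carry macrostate-dependent means and exact
          per-residue decompositions", {
  ## zero noise: every record equals its macrostate mean
  sp0 <- energyGeneratorSpec(c(-50, -20), noiseSd = 0, seed = 1)
  tab0 <- generateEnergyTable(sp0, c(1, 1, 2))
  rec0 <- energyRecords(tab0)
  expect_equal(rec0$total, rep(c(-50, -50, -20), each = 10))

  ## noisy means recovered within 3 SE by direct averaging
  sp <- energyGeneratorSpec(c(-50, -20), noiseSd = 3,
                            nFramesPerMicro = 200, seed = 2)
  tab <- generateEnergyTable(sp, c(1, 2))
  rec <- energyRecords(tab)
  m1 <- rec$total[rec$microstate == 1]
  expect_lt(abs(mean(m1) + 50), 3 * sd(m1) / sqrt(length(m1)))

  ## per-residue columns sum to the total and carry the fractions
  spr <- energyGeneratorSpec(c(-40), noiseSd = 1,
                             perResidueFractions = c(0.9, 0.1), seed = 3)
  tabr <- generateEnergyTable(spr, 1L)
  recr <- energyRecords(tabr)
  expect_equal(recr$`residue:1` + recr$`residue:2`, recr$total,
               tolerance = 1e-12)
  expect_equal(recr$`residue:2` / recr$total, rep(0.1, 10))

  expect_error(generateEnergyTable(sp0, integer()), "empty")
  expect_error(generateEnergyTable(sp0, c(1, 3)), "unknown macrostate")
})
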