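## a minimal hand-built frame for arithmetic checks
miniGroups <- function() {
  list(large_domain_CA = 1:2, small_domain_CA = 3:4, probe_pair = c(1L, 3L),
       ligand_heavy = 5L)
}

test_that("probe distance is plain Euclidean geometry", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0), c(3, 5, 0), c(2, 2, 2))
  ens <- makeEnsemble(list(co), miniGroups())
  expect_equal(calcProbeDistance(ens), 5)  # 3-4-5 triangle

  co2 <- co; co2[3, ] <- co2[1, ]
  expect_equal(calcProbeDistance(makeEnsemble(list(co2), miniGroups())), 0)

  g <- miniGroups(); g$probe_pair <- NULL
  expect_error(calcProbeDistance(makeEnsemble(list(co), g)), "probe_pair")
})

test_that("ligand displacement is the mean-distance difference and is
          antisymmetric under domain exchange", {
  ## 1 ligand atom at origin; small-domain atoms at distances 2 and 4,
  ## large-domain atoms both at distance 1: mean difference = 3 - 1 = 2
  co <- rbind(c(1, 0, 0), c(0, 1, 0),       # large, both |.| = 1
              c(2, 0, 0), c(0, 4, 0),       # small, |.| = 2 and 4
              c(0, 0, 0))                   # ligand
  ens <- makeEnsemble(list(co), miniGroups())
  expect_equal(calcLigandDisplacement(ens), 2)

  gSwap <- miniGroups()
  gSwap[c("large_domain_CA", "small_domain_CA")] <-
    gSwap[c("small_domain_CA", "large_domain_CA")]
  expect_equal(calcLigandDisplacement(makeEnsemble(list(co), gSwap)), -2)

  ## equidistant from mirror-symmetric domains: zero
  geo <- defaultGeometryConfig(jitter = 0)
  e0 <- buildPseudoStructures("S1p", geo, seed = 1)
  expect_equal(calcLigandDisplacement(e0), 0, tolerance = 1e-7)
})

test_that("pocket rearrangement uses C-alpha centroid distances and is
          rigid-motion invariant", {
  g <- list(strandJ = 1L, helixV = 2L, helixVI = 3L)
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0))
  ens <- makeEnsemble(list(co), g)
  expect_equal(calcPocketRearrangement(ens), 2 - 3)  # d1 = 2, d2 = 3

  ## translation + rotation leave it unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- sweep(co %*% t(R), 2L, c(10, -3, 5), "+")
  expect_equal(calcPocketRearrangement(makeEnsemble(list(co2), g)),
               -1, tolerance = 1e-12)

  ## d1 == d2 by construction gives zero
  co3 <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  expect_equal(calcPocketRearrangement(makeEnsemble(list(co3), g)), 0)
})

test_that("hinge H-bond counting applies the 3.5 A criterion and the
          bootstrap matches the binomial oracle", {
  hbFrame <- function(d) {
    co <- do.call(rbind, lapply(seq_along(d), function(j)
      rbind(c(0, 3 * j, 0), c(d[j], 3 * j, 0))))
    co
  }
  g <- list(hbond_pairs = 1:8)
  ens <- makeEnsemble(list(hbFrame(rep(2.8, 4)),
                           hbFrame(c(3.4, 3.6, 2.0, 5.0))), g)
  expect_equal(countHingeHbonds(ens), c(4L, 2L))

  ## frames split 50/50 between all-4 and all-0 bonds: bootstrap mean of
  ## the total is 2.0 with the closed-form binomial SE
  frames <- c(replicate(40, hbFrame(rep(2.8, 4)), simplify = FALSE),
              replicate(40, hbFrame(rep(5.0, 4)), simplify = FALSE))
  ens2 <- makeEnsemble(frames, g)
  bs <- bootstrapHbondStats(list(A = ens2), nSamples = 200,
                            sampleSize = 100, seed = 9)
  tot <- bs[bs$pair == "total", ]
  seBinom <- 4 * sqrt(0.25 / 100)   # sd of the resampled mean count
  expect_lt(abs(tot$mean - 2), 3 * seBinom / sqrt(200))
  expect_equal(tot$sd, seBinom, tolerance = 0.15)

  expect_warning(bootstrapHbondStats(list(A = makeEnsemble(
    frames[1:5], g)), nSamples = 10, sampleSize = 20, seed = 1),
    "fewer than 10 frames")
})

test_that("feature matrix selection and assembly follow the contact
          cutoff", {
  geo <- defaultGeometryConfig(jitter = 0)
  refs <- defaultReferenceStructures(geo)
  ens <- buildPseudoStructures(c("S1", "S1"), geo, seed = 1)

  ## finite cutoff: 2 contact residues per domain ->
  ## 2x2 pairs + 4 ligand columns + probe = 9
  fm <- buildFeatureMatrix(ens, refs, cutoff = 9)
  expect_equal(ncol(featureValues(fm)), 9L)
  expect_true("probe" %in% colnames(featureValues(fm)))

  ## infinite cutoff: all inter-domain pairs selected
  fmAll <- buildFeatureMatrix(ens, refs, cutoff = Inf)
  nL <- length(atomGroups(ens)$large_domain_CA)
  expect_equal(ncol(featureValues(fmAll)), nL * nL + 2L * nL + 1L)

  ## identical frames give identical rows
  expect_equal(featureValues(fm)[1, ], featureValues(fm)[2, ])

  ## tiny cutoff: nothing selected
  expect_error(buildFeatureMatrix(ens, refs, cutoff = 0.1),
               "increase the cutoff")

  ## all features are invariant under a rigid-body transform per frame
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- lapply(ens@frames, function(f)
    sweep(f %*% t(R), 2L, c(5, 6, 7), "+"))
  ensM <- makeEnsemble(moved, atomGroups(ens))
  fmM <- buildFeatureMatrix(ensM, refs, cutoff = 9)
  expect_equal(featureValues(fmM), featureValues(fm), tolerance = 1e-10)
})
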