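pipelineDefaults <- function() {
  list(
    seed = 1L,
    synthetic = list(nTraj = 40L, nSteps = 2000L, jitter = 0.3),
    msm = list(cutoff = 9, nTics = 4L, ticaLag = 10L, nClusters = 750L,
               minCount = 15L, msmLag = 30L, nEigen = 5L),
    kinetics = list(nMacro = 8L, mcTraj = 100L, mcLength = 10000L,
                    burnInFrac = 1 / 3),
    energetics = list(nIter = 1000L, noiseSd = 2,
                      macroMeanEnergies = c(-150, -152, -149, -168,
                                            -163, -185, -151, -160)),
    smfret = list(nTraces = 50L, traceLength = 500L, nStates = NULL,
                  tdpSigma = 0.03),
    hbond = list(nSamples = 100L, sampleSize = 100L))
}

checkKeys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad))
    stop("unknown config key: ", path, bad[1L], call. = FALSE)
  for (nm in names(x)) {
    if (is.list(ref[[nm]]) && !is.null(x[[nm]])) {
      if (!is.list(x[[nm]]))
        stop("config key ", path, nm, " must be a block", call. = FALSE)
      checkKeys(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
    }
  }
}

#' Pipeline configuration
#'
#' Validated nested configuration for the end-to-end synthetic pipeline.
#' MSM defaults follow the reference analysis of the two-domain binding
#' protein: 9 A feature cutoff, 4 tICs, tICA lag 10 ns, 750 k-center
#' microstates pruned at 15 frames, MSM lag 30 ns, 8 macrostates,
#' Monte-Carlo kinetics from 100 trajectories with the first third
#' discarded, 1000 energy-bootstrap iterations and a 100 x 100 H-bond
#' bootstrap.  Synthetic-data sizes (trajectory counts/lengths) default to
#' desk-scale values.  Unknown keys are rejected with the offending key
#' path named.
#'
#' @param ... overrides of the default blocks (partial lists allowed),
#'   e.g. \code{msm = list(nClusters = 100)}.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  cfg <- pipelineDefaults()
  checkKeys(over, cfg)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]])) cfg[[nm]] <- utils::modifyList(cfg[[nm]],
                                                           over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$msm$cutoff > 0, cfg$msm$nTics >= 1,
            cfg$msm$nClusters >= 2, cfg$kinetics$nMacro >= 1,
            cfg$kinetics$burnInFrac > 0, cfg$kinetics$burnInFrac < 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in \code{\link{pipelineConfig}}.
#' @return A validated \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

configChecksum <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
            .Machine$integer.max)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates the eight-macrostate fixture network, samples microstate
#' trajectories, realizes them as pseudo-structures, featurizes, builds
#' and validates the MSM (tICA, k-center, pruning, symmetrized
#' estimation), lumps with PCCA+, computes Monte-Carlo kinetics against
#' the closed-form oracles, aggregates synthetic binding energies, and
#' runs the smFRET branch (trace generation, HMM, TDP, thresholds,
#' populations).  Returns a nested report; with \code{outDir}, stage
#' outputs and a JSON report + run manifest are written.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  report <- list(config = unclass(config),
                 configChecksum = configChecksum(config))

  ## --- synthetic network + structures + features
  netSpec <- fixtureNetworkFig2()
  T0 <- buildNetworkMatrix(netSpec, seed = subSeed(seed, 1L))
  microToMacro <- attr(T0@matrix, "microToMacro")
  trajs <- sampleDiscreteTrajectories(T0, config$synthetic$nTraj,
                                      config$synthetic$nSteps,
                                      seed = subSeed(seed, 2L))
  macroLabels <- netSpec$macroNames[
    microToMacro[unlist(trajs, use.names = FALSE)]]
  geo <- defaultGeometryConfig(jitter = config$synthetic$jitter)
  ens <- buildPseudoStructures(macroLabels, geo, seed = subSeed(seed, 3L))
  fm <- buildFeatureMatrix(ens, defaultReferenceStructures(geo),
                           cutoff = config$msm$cutoff,
                           frameInterval = netSpec$lagUnit,
                           trajLengths = rep(config$synthetic$nSteps,
                                             config$synthetic$nTraj))
  report$features <- list(nFrames = nrow(fm@values),
                          nFeatures = ncol(fm@values))

  ## --- MSM (lags here are in frames; one frame = one network step)
  tica <- fitTica(fm, lag = max(1L, config$msm$ticaLag %/%
                                  as.integer(netSpec$lagUnit)),
                  nComponents = config$msm$nTics)
  proj <- projectData(tica, fm)
  km <- kcenterCluster(proj, k = min(config$msm$nClusters,
                                     nrow(proj) %/% 20L),
                       seed = subSeed(seed, 4L),
                       trajLengths = fm@trajLengths)
  km <- pruneStates(km, minCount = config$msm$minCount)
  msmLagFrames <- max(1L, config$msm$msmLag %/%
                        as.integer(netSpec$lagUnit))
  Tm <- estimateTransitionMatrix(km@assignments, lag = msmLagFrames,
                                 frameInterval = netSpec$lagUnit)
  report$msm <- list(nMicrostates = nrow(Tm@matrix),
                     lag = Tm@lag,
                     ticaEigenvalues = tica@eigenvalues[
                       seq_len(tica@nComponentsKept)])

  ## --- kinetics
  macro <- lumpPcca(Tm, config$kinetics$nMacro)
  kin <- mcKinetics(Tm, macro, nTraj = config$kinetics$mcTraj,
                    length = config$kinetics$mcLength,
                    burnIn = as.integer(config$kinetics$mcLength *
                                          config$kinetics$burnInFrac),
                    seed = subSeed(seed, 5L))
  piMicro <- stationaryDistribution(Tm)
  piMacro <- vapply(seq_len(macro@nMacro), function(a)
    sum(piMicro[macro@microToMacro == a]), numeric(1))
  report$kinetics <- list(
    mcPopulations = kin@populations, exactPopulations = piMacro,
    mfpt = kin@mfpt, mfptExact = mfptExactTable(Tm, macro))

  ## --- energetics on the fixture microstates
  eSpec <- energyGeneratorSpec(
    config$energetics$macroMeanEnergies[seq_len(netSpec$nMacro)],
    noiseSd = config$energetics$noiseSd,
    perResidueFractions = c(0.9, 0.1), seed = subSeed(seed, 6L))
  eTab <- generateEnergyTable(eSpec, microToMacro)
  agg <- aggregateBindingEnergies(
    eTab, attr(T0@matrix, "stationary"), microToMacro,
    nIter = config$energetics$nIter, seed = subSeed(seed, 7L),
    macroNames = netSpec$macroNames)
  report$energetics <- agg

  ## --- smFRET branch
  fSpec <- fixtureSmfretFig6(traceLength = config$smfret$traceLength,
                             nTraces = config$smfret$nTraces,
                             seed = subSeed(seed, 8L))
  traces <- generateFretTraces(fSpec)
  hmm <- fitHmm(traces, nStates = config$smfret$nStates,
                seed = subSeed(seed, 9L))
  tdp <- buildTdp(hmm, sigma = config$smfret$tdpSigma)
  fit6 <- fitTdpGaussians(tdp, seed = subSeed(seed, 10L))
  thr <- deriveThresholds(fit6)
  pops <- statePopulations(hmm, thr)
  report$smfret <- list(nStates = hmm@nStates, means = hmm@means,
                        thresholds = thr@bounds,
                        populations = pops$populations,
                        unassigned = pops$unassigned)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureMatrix(fm, file.path(outDir, "features.csv"))
    writeTransitionMatrix(Tm, file.path(outDir, "transition_matrix.json"))
    writeFretTraces(traces, file.path(outDir, "fret_traces.csv"))
    writeEnergyTable(eTab, file.path(outDir, "energies.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(
      list(configChecksum = report$configChecksum, seed = seed,
           rVersion = as.character(getRversion()),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(report)
}
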