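fixturePath <- function(name) {
  p <- system.file("extdata", "fixtures", name, package = "msmfret")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

#' Eight-macrostate kinetic network fixture
#'
#' Loads the packaged synthetic eight-state network specification
#' (macrostate stationary populations and the intra-/inter-cluster
#' transition propensities of a two-domain binding network: a
#' small-domain-bound cluster S1-S3, a large-domain-bound cluster S4-S6
#' bridged through the semi-closed states, and two slow off-pathway states
#' S1', S4').  The populations honour the published constraints that the
#' three ligand-induced closed states (S1, S1', S4') together hold 24% and
#' the ligand-induced open state S2 about 4%; individual values are a
#' synthetic transcription, documented in the fixture file.
#'
#' @return A \code{\link{kineticNetworkSpec}}.  The attribute
#'   \code{"ligandInducedClosed"} names the three ligand-induced closed
#'   macrostates.
#' @export
fixtureNetworkFig2 <- function() {
  fx <- jsonlite::read_json(fixturePath("network_fig2.json"),
                            simplifyVector = TRUE)
  nm <- fx$macro_names
  n <- length(nm)
  R <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(nrow(fx$edges))) {
    a <- fx$edges$a[i]; b <- fx$edges$b[i]
    R[a, b] <- R[b, a] <- fx$edges$rate[i]
  }
  spec <- kineticNetworkSpec(
    macroPopulations = fx$populations_percent / 100,
    nMicroPerMacro = fx$n_micro_per_macro,
    intraRate = fx$intra_rate, interRateMatrix = R,
    lagUnit = fx$lag_unit_ns, macroNames = nm)
  attr(spec, "ligandInducedClosed") <- fx$ligand_induced_closed
  spec
}

#' Four-state smFRET fixture
#'
#' Loads the packaged four-state FRET trace generator specification whose
#' emission means (0.15, 0.31, 0.51, 0.68) and stationary populations
#' (24, 23, 33, 20 percent) are the published values for the four
#' efficiency states of the ligand-bound protein; the hidden chain is a
#' Metropolis chain with uniform symmetric proposal and those populations
#' as its stationary vector.
#'
#' @param traceLength,nTraces,seed overrides for the generated trace set.
#' @return A \code{\link{fretGeneratorSpec}}.
#' @export
fixtureSmfretFig6 <- function(traceLength = 1000L, nTraces = 100L,
                              seed = 1L) {
  fx <- jsonlite::read_json(fixturePath("smfret_fig6.json"),
                            simplifyVector = TRUE)
  Q <- matrix(fx$proposal_rate, length(fx$populations),
              length(fx$populations))
  chain <- metropolisMatrix(fx$populations, Q)
  fretGeneratorSpec(emissionMeans = fx$emission_means,
                    emissionSds = fx$emission_sd, chainMatrix = chain,
                    frameInterval = fx$frame_interval_s,
                    traceLength = traceLength, nTraces = nTraces,
                    seed = seed)
}
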