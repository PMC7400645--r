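#' Binding-energy table generator specification
#'
#' Per-frame binding energies drawn about macrostate-dependent means, with
#' optional per-residue decomposition: each record's residue energies are
#' fixed fractions of its total, so they sum to the total exactly.
#'
#' @param macroMeanEnergies mean binding energy per macrostate (kJ/mol;
#'   more negative = more favorable).
#' @param noiseSd record-level Gaussian noise (kJ/mol), >= 0.
#' @param perResidueFractions optional probability vector of per-residue
#'   shares of the total energy (must sum to 1).
#' @param nFramesPerMicro records generated per microstate (>= 10; ten
#'   conformations per microstate is the reference sampling depth).
#' @param seed integer seed.
#' @return A validated list of class \code{"EnergyGeneratorSpec"}.
#' @export
energyGeneratorSpec <- function(macroMeanEnergies, noiseSd = 2,
                                perResidueFractions = NULL,
                                nFramesPerMicro = 10L, seed = 1L) {
  if (!length(macroMeanEnergies)) stop("need at least one macrostate mean")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(perResidueFractions)) {
    if (abs(sum(perResidueFractions) - 1) > 1e-9)
      stop("perResidueFractions must sum to 1")
  }
  if (nFramesPerMicro < 10L)
    stop("nFramesPerMicro must be >= 10")
  structure(list(macroMeanEnergies = macroMeanEnergies, noiseSd = noiseSd,
                 perResidueFractions = perResidueFractions,
                 nFramesPerMicro = as.integer(nFramesPerMicro),
                 seed = as.integer(seed)),
            class = "EnergyGeneratorSpec")
}

#' Generate a per-frame binding-energy table
#'
#' @param spec an \code{\link{energyGeneratorSpec}}.
#' @param assignment integer macrostate label per microstate (microstate i
#'   is row i); every macrostate index must be valid for the spec's means.
#' @return An \linkS4class{EnergyTable} with \code{nFramesPerMicro} records
#'   per microstate; per-residue columns \code{residue:<j>} when fractions
#'   are given.
#' @export
generateEnergyTable <- function(spec, assignment) {
  stopifnot(inherits(spec, "EnergyGeneratorSpec"))
  assignment <- as.integer(assignment)
  if (!length(assignment)) stop("empty microstate assignment")
  if (any(assignment < 1L | assignment > length(spec$macroMeanEnergies)))
    stop("assignment references unknown macrostate")
  nMicro <- length(assignment)
  nf <- spec$nFramesPerMicro
  localSeed(spec$seed, {
    total <- rep(spec$macroMeanEnergies[assignment], each = nf) +
      rnorm(nMicro * nf, sd = spec$noiseSd)
    rec <- data.frame(microstate = rep(seq_len(nMicro), each = nf),
                      frame = rep(seq_len(nf), times = nMicro),
                      total = total)
    if (!is.null(spec$perResidueFractions)) {
      fr <- spec$perResidueFractions
      for (j in seq_along(fr))
        rec[[paste0("residue:", j)]] <- total * fr[j]
    }
    new("EnergyTable", records = rec)
  })
}
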