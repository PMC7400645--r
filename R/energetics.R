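#' Population-weighted bootstrap aggregation of binding energies
#'
#' Per iteration, one record is drawn at random from every microstate; the
#' binding free energy of a macrostate is the weighted sum of its
#' microstates' drawn energies with weights \eqn{\pi_i / \sum_{i \in
#' macro} \pi_i} (relative microstate populations within the macrostate),
#' and the ensemble energy is \eqn{\sum_i \pi_i E_i} over all microstates.
#' Means and standard deviations are reported over the iterations.
#'
#' @param table an \linkS4class{EnergyTable}.
#' @param microPopulations stationary population per microstate (strictly
#'   positive on every microstate present in the table).
#' @param macro a \linkS4class{MacrostateModel} (or integer macrostate
#'   label per microstate).
#' @param nIter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param macroNames optional names for the report rows.
#' @return List with \code{perMacrostate} (data.frame: macrostate, mean,
#'   sd), \code{ensemble} (mean, sd), \code{nIter}, \code{seed}.
#' @export
aggregateBindingEnergies <- function(table, microPopulations, macro,
                                     nIter = 1000L, seed = 1L,
                                     macroNames = NULL) {
  stopifnot(is(table, "EnergyTable"))
  m2m <- if (is(macro, "MacrostateModel")) macro@microToMacro
         else as.integer(macro)
  rec <- table@records
  nMicro <- length(m2m)
  present <- sort(unique(rec$microstate))
  missing <- setdiff(seq_len(nMicro), present)
  if (length(missing))
    stop("microstate(s) with no energy records: ",
         paste(missing, collapse = ", "))
  if (length(microPopulations) != nMicro ||
      any(microPopulations[present] <= 0))
    stop("microPopulations must be strictly positive for all ", nMicro,
         " microstates")
  nMacro <- max(m2m)
  if (is.null(macroNames)) macroNames <- paste0("M", seq_len(nMacro))
  byMicro <- split(rec$total, rec$microstate)
  wEns <- microPopulations / sum(microPopulations)
  wMac <- lapply(seq_len(nMacro), function(a) {
    i <- which(m2m == a)
    list(idx = i, w = microPopulations[i] / sum(microPopulations[i]))
  })
  draws <- localSeed(seed, {
    vapply(seq_len(nIter), function(it) {
      E <- vapply(byMicro, function(v)
        v[sample.int(length(v), 1L)], numeric(1))
      c(vapply(wMac, function(g) sum(g$w * E[g$idx]), numeric(1)),
        sum(wEns * E))
    }, numeric(nMacro + 1L))
  })
  draws <- matrix(draws, nrow = nMacro + 1L)
  perMac <- data.frame(macrostate = macroNames,
                       mean = rowMeans(draws)[seq_len(nMacro)],
                       sd = apply(draws, 1L, sd)[seq_len(nMacro)])
  list(perMacrostate = perMac,
       ensemble = c(mean = rowMeans(draws)[nMacro + 1L],
                    sd = apply(draws, 1L, sd)[nMacro + 1L]),
       nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Bootstrap per-residue contribution fraction
#'
#' Same one-record-per-microstate bootstrap scheme as
#' \code{\link{aggregateBindingEnergies}}, reporting the
#' population-weighted mean of (residue energy / total energy).  Draws in
#' which the weighted total crosses zero are flagged and excluded, with
#' the count reported.
#'
#' @param table an \linkS4class{EnergyTable} with per-residue columns.
#' @param residueId residue identifier (the \code{j} of column
#'   \code{residue:j}) or full column name.
#' @param weights microstate weights (e.g. stationary populations
#'   restricted to the microstates of one macrostate); zero weight
#'   excludes a microstate.
#' @param nIter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return List with \code{fraction}, \code{sd}, \code{nExcluded},
#'   \code{nIter}.
#' @export
residueContributionFraction <- function(table, residueId, weights,
                                        nIter = 1000L, seed = 1L) {
  stopifnot(is(table, "EnergyTable"))
  rec <- table@records
  col <- if (residueId %in% names(rec)) residueId
         else paste0("residue:", residueId)
  if (!col %in% names(rec)) stop("no per-residue column '", col, "'")
  micro <- sort(unique(rec$microstate))
  if (length(weights) != length(micro))
    stop("need one weight per microstate present in the table")
  use <- which(weights > 0)
  w <- weights[use] / sum(weights[use])
  byMicro <- split(rec[, c("total", col)], rec$microstate)
  byMicro <- byMicro[as.character(micro[use])]
  res <- localSeed(seed, {
    vapply(seq_len(nIter), function(it) {
      picks <- vapply(byMicro, function(d) {
        i <- sample.int(nrow(d), 1L)
        c(d$total[i], d[[col]][i])
      }, numeric(2))
      tot <- sum(w * picks[1L, ])
      resid <- sum(w * picks[2L, ])
      if (abs(tot) < 1e-12) NA_real_ else resid / tot
    }, numeric(1))
  })
  bad <- sum(is.na(res))
  list(fraction = mean(res, na.rm = TRUE), sd = sd(res, na.rm = TRUE),
       nExcluded = bad, nIter = as.integer(nIter))
}

#' Dissociation constant to standard binding free energy
#'
#' \eqn{\Delta G = RT \ln(K_d / 1\,\mathrm{M})} with \eqn{R} = 8.314 J/mol/K
#' and the 1 M standard state; negative for sub-molar affinities.
#'
#' @param kd dissociation constant in molar, > 0.
#' @param temperature Kelvin, > 0.
#' @return Free energy in kJ/mol.
#' @export
kdToDeltaG <- function(kd, temperature) {
  if (any(kd <= 0) || any(temperature <= 0))
    stop("kd and temperature must be > 0")
  8.314e-3 * temperature * log(kd)
}

#' Affinity fold change between two dissociation constants
#'
#' @param kdA,kdB dissociation constants (same units), > 0.
#' @return \code{kdA / kdB}.
#' @export
foldChange <- function(kdA, kdB) {
  if (any(kdA <= 0) || any(kdB <= 0)) stop("kd values must be > 0")
  kdA / kdB
}
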