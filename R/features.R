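groupCoords <- function(ens, frame, group) {
  idx <- ens@atomGroups[[group]]
  if (is.null(idx) || !length(idx))
    stop("atom group '", group, "' is missing or empty")
  frame[idx, , drop = FALSE]
}

#' FRET probe distance per frame
#'
#' Euclidean distance between the two probe atoms (the C-alpha positions
#' carrying the donor and acceptor dyes, one in each domain) — the
#' open/closed order parameter d_FRET.
#'
#' @param ens a \linkS4class{ConformationEnsemble} with a
#'   \code{probe_pair} group.
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
calcProbeDistance <- function(ens) {
  stopifnot(is(ens, "ConformationEnsemble"))
  idx <- ens@atomGroups$probe_pair
  if (is.null(idx) || length(idx) != 2L)
    stop("atom group 'probe_pair' is missing or not a pair")
  vapply(ens@frames, function(f)
    sqrt(sum((f[idx[1L], ] - f[idx[2L], ])^2)), numeric(1))
}

#' Ligand displacement between domains per frame
#'
#' \eqn{\Delta d = \bar d(\mathrm{ligand, small}) - \bar
#' d(\mathrm{ligand, large})}: the mean over all ligand-heavy-atom x
#' small-domain-C-alpha pairwise distances minus the corresponding mean
#' for the large domain.  Negative values place the ligand at the small
#' domain; the sign flips if the domain group labels are exchanged.
#'
#' @param ens a \linkS4class{ConformationEnsemble} with
#'   \code{ligand_heavy}, \code{small_domain_CA} and
#'   \code{large_domain_CA} groups.
#' @return Numeric vector (Angstrom) per frame.
#' @export
calcLigandDisplacement <- function(ens) {
  stopifnot(is(ens, "ConformationEnsemble"))
  vapply(ens@frames, function(f) {
    lig <- groupCoords(ens, f, "ligand_heavy")
    mean(crossDist(lig, groupCoords(ens, f, "small_domain_CA"))) -
      mean(crossDist(lig, groupCoords(ens, f, "large_domain_CA")))
  }, numeric(1))
}

#' Small-domain pocket rearrangement per frame
#'
#' \eqn{\Delta d = d_1 - d_2} with \eqn{d_1} the helixVI-helixV and
#' \eqn{d_2} the helixV-strandJ distance, each measured between the
#' C-alpha centroids of the groups (simple, rotation-invariant and
#' monotone with pocket width).  Small values mean the small-domain pocket
#' is locked; large values mean it is open enough to accommodate the
#' ligand.
#'
#' @param ens a \linkS4class{ConformationEnsemble} with \code{helixV},
#'   \code{helixVI} and \code{strandJ} groups.
#' @return Numeric vector (Angstrom) per frame.
#' @export
calcPocketRearrangement <- function(ens) {
  stopifnot(is(ens, "ConformationEnsemble"))
  vapply(ens@frames, function(f) {
    cV <- colMeans(groupCoords(ens, f, "helixV"))
    cVI <- colMeans(groupCoords(ens, f, "helixVI"))
    cJ <- colMeans(groupCoords(ens, f, "strandJ"))
    sqrt(sum((cVI - cV)^2)) - sqrt(sum((cV - cJ)^2))
  }, numeric(1))
}

hbondDistances <- function(ens) {
  idx <- ens@atomGroups$hbond_pairs
  if (is.null(idx) || length(idx) != 8L)
    stop("atom group 'hbond_pairs' must contain 4 donor-acceptor pairs")
  t(vapply(ens@frames, function(f) {
    vapply(1:4, function(j)
      sqrt(sum((f[idx[2L * j - 1L], ] - f[idx[2L * j], ])^2)), numeric(1))
  }, numeric(4)))
}

#' Count formed hinge hydrogen bonds per frame
#'
#' A donor-acceptor pair counts as bonded when its heavy-atom distance is
#' at most \code{cutoff} (no angle criterion: toy structures carry no
#' hydrogens).
#'
#' @param ens a \linkS4class{ConformationEnsemble} with a
#'   \code{hbond_pairs} group (4 pairs).
#' @param cutoff bond distance criterion (Angstrom, default 3.5).
#' @return Integer vector in 0..4, one count per frame.
#' @export
countHingeHbonds <- function(ens, cutoff = 3.5) {
  d <- hbondDistances(ens)
  as.integer(rowSums(d <= cutoff))
}

#' Bootstrap per-pair hinge H-bond statistics by state
#'
#' For each state's ensemble, resamples \code{sampleSize} frames with
#' replacement \code{nSamples} times and reports the per-pair
#' bonded-fraction mean and sd over the resamples (plus the mean and sd of
#' the total bond count).
#'
#' @param ensPerState named list of \linkS4class{ConformationEnsemble}
#'   objects, one per state.
#' @param nSamples bootstrap samples (default 100).
#' @param sampleSize frames per sample (default 100); sampling is always
#'   with replacement, and a warning is emitted below 10 available frames.
#' @param cutoff H-bond distance criterion (Angstrom).
#' @param seed integer seed.
#' @return data.frame with columns \code{state}, \code{pair} (1..4 or
#'   \code{"total"}), \code{mean}, \code{sd}.
#' @export
bootstrapHbondStats <- function(ensPerState, nSamples = 100L,
                                sampleSize = 100L, cutoff = 3.5,
                                seed = 1L) {
  stopifnot(is.list(ensPerState), length(ensPerState) >= 1L)
  localSeed(seed, {
    res <- lapply(names(ensPerState), function(st) {
      d <- hbondDistances(ensPerState[[st]])
      bonded <- d <= cutoff
      n <- nrow(bonded)
      if (n < 10L)
        warning("state ", st, " has only ", n, " frames; bootstrap on ",
                "fewer than 10 frames is unreliable")
      stats <- replicate(nSamples, {
        i <- sample.int(n, sampleSize, replace = TRUE)
        c(colMeans(bonded[i, , drop = FALSE]),
          mean(rowSums(bonded[i, , drop = FALSE])))
      })
      data.frame(state = st, pair = c(as.character(1:4), "total"),
                 mean = rowMeans(stats), sd = apply(stats, 1L, sd))
    })
    do.call(rbind, res)
  })
}

#' Build the tICA input feature matrix from an ensemble
#'
#' Selects the domain "residues" (C-alpha atoms) having any atom within
#' \code{cutoff} of any ligand heavy atom in at least one of the reference
#' structures, then assembles, per frame: all inter-domain C-alpha pair
#' distances over the selection, the mean ligand-heavy-atom distance to
#' each selected C-alpha, and the probe-pair distance.  Column names are
#' stable: \code{dd_L<i>_S<j>}, \code{lig_L<i>}/\code{lig_S<j>},
#' \code{probe}.
#'
#' @param ens a \linkS4class{ConformationEnsemble}.
#' @param referenceStructures list of one or more single-frame
#'   \linkS4class{ConformationEnsemble} objects (e.g. a ligand-bound
#'   closed structure and a representative small-domain-bound closed
#'   conformation) used only for residue selection; defaults to the first
#'   frame of \code{ens}.
#' @param cutoff selection distance (Angstrom, default 9).
#' @param frameInterval frame spacing in ns for the output.
#' @param trajLengths optional partition of frames into trajectories
#'   (default: one trajectory).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(ens, referenceStructures = NULL, cutoff = 9,
                               frameInterval = 1, trajLengths = NULL) {
  stopifnot(is(ens, "ConformationEnsemble"))
  if (is.null(referenceStructures))
    referenceStructures <- list(
      new("ConformationEnsemble", frames = ens@frames[1L],
          atomGroups = ens@atomGroups))
  gl <- ens@atomGroups$large_domain_CA
  gs <- ens@atomGroups$small_domain_CA
  selL <- rep(FALSE, length(gl)); selS <- rep(FALSE, length(gs))
  for (ref in referenceStructures) {
    f <- ref@frames[[1L]]
    lig <- groupCoords(ref, f, "ligand_heavy")
    selL <- selL | apply(crossDist(f[gl, , drop = FALSE], lig), 1L, min) <= cutoff
    selS <- selS | apply(crossDist(f[gs, , drop = FALSE], lig), 1L, min) <= cutoff
  }
  if (!any(selL) || !any(selS))
    stop("no residues selected at cutoff ", cutoff,
         " A; increase the cutoff")
  iL <- gl[selL]; iS <- gs[selS]
  nmL <- paste0("L", which(selL)); nmS <- paste0("S", which(selS))
  pairNames <- as.vector(outer(nmL, nmS, function(a, b)
    paste0("dd_", a, "_", b)))
  cols <- c(pairNames, paste0("lig_", c(nmL, nmS)), "probe")
  pidx <- ens@atomGroups$probe_pair
  vals <- t(vapply(ens@frames, function(f) {
    dd <- as.vector(crossDist(f[iL, , drop = FALSE], f[iS, , drop = FALSE]))
    lig <- groupCoords(ens, f, "ligand_heavy")
    ligd <- colMeans(crossDist(lig, f[c(iL, iS), , drop = FALSE]))
    pr <- sqrt(sum((f[pidx[1L], ] - f[pidx[2L], ])^2))
    c(dd, ligd, pr)
  }, numeric(length(cols))))
  colnames(vals) <- cols
  if (is.null(trajLengths)) trajLengths <- nrow(vals)
  new("FeatureMatrix", values = vals, frameInterval = frameInterval,
      trajLengths = as.integer(trajLengths))
}
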