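## Fixed local-offset templates.  Domain C-alpha clusters are symmetric
## about their centroid so that centroid placement is exact; the probe atom
## of each domain sits at the centroid itself.
domainOffsets <- function() {
  rbind(c(0.8, 0.8, 0), c(-0.8, -0.8, 0), c(0.8, -0.8, 0.6),
        c(-0.8, 0.8, -0.6))
}

pocketOffsets <- function() {
  rbind(c(0, 0.6, 0), c(0.5, -0.3, 0.3), c(-0.5, -0.3, -0.3))
}

#' Per-state geometry targets for pseudo-structures
#'
#' Target values of the structural order parameters realized by
#' \code{\link{buildPseudoStructures}} for each macrostate label: FRET
#' probe distance (Angstrom), ligand displacement (mean ligand-small-domain
#' minus mean ligand-large-domain distance), pocket rearrangement
#' (helixVI-helixV minus helixV-strandJ centroid distance) and the four
#' hinge hydrogen-bond donor-acceptor distances.
#'
#' @param states named list; each element a list with fields \code{probe},
#'   \code{ligandDd}, \code{pocketDd}, \code{hbond} (length-4 numeric).
#' @param jitter Gaussian coordinate noise sd (Angstrom) applied atom-wise.
#' @param d2 fixed helixV-strandJ reference distance (Angstrom).
#' @return A validated list of class \code{"GeometryConfig"}.
#' @export
geometryConfig <- function(states, jitter = 0.3, d2 = 10) {
  stopifnot(is.list(states), length(states) >= 1L,
            !is.null(names(states)))
  for (nm in names(states)) {
    s <- states[[nm]]
    if (!all(c("probe", "ligandDd", "pocketDd", "hbond") %in% names(s)))
      stop("state '", nm, "' needs probe, ligandDd, pocketDd, hbond")
    if (s$probe <= 0) stop("probe distance must be > 0 for state ", nm)
    if (d2 + s$pocketDd <= 0)
      stop("infeasible pocket geometry (d1 <= 0) for state ", nm)
    if (length(s$hbond) != 4L || any(s$hbond <= 0))
      stop("hbond must be 4 positive distances for state ", nm)
  }
  if (jitter < 0) stop("jitter must be >= 0")
  structure(list(states = states, jitter = jitter, d2 = d2),
            class = "GeometryConfig")
}

#' Default eight-state geometry
#'
#' Targets chosen to mirror the qualitative pattern of a two-domain
#' binding protein with eight macrostates: closed states (S1, S6, S1', S4')
#' near 35-36 A probe distance, open states S2/S5 at 43.1/46.1 A,
#' semi-closed S3/S4 in between; ligand displacement negative for
#' small-domain binding (S1-S3), positive for large-domain binding
#' (S4-S6), near zero at the interface (S1', S4'); pocket rearrangement
#' large where the small-domain pocket is open (S1, S2, S1') and small
#' where it is locked (S5, S6, S4'); hinge hydrogen bonds mostly formed for
#' large-domain binding and progressively lost as the ligand migrates, with
#' S1' showing the swapped bonding pattern (first pair broken, second pair
#' formed) that distinguishes it from S1.
#'
#' @inheritParams geometryConfig
#' @return A \code{"GeometryConfig"} for states S1..S6, S1p, S4p.
#' @export
defaultGeometryConfig <- function(jitter = 0.3) {
  on <- 2.9; off <- 4.5
  geometryConfig(list(
    S1  = list(probe = 35.0, ligandDd = -8, pocketDd =  4,
               hbond = c(on, off, off, off)),
    S2  = list(probe = 43.1, ligandDd = -8, pocketDd =  4,
               hbond = c(on, off, off, off)),
    S3  = list(probe = 39.0, ligandDd = -8, pocketDd =  1,
               hbond = c(on, on, off, off)),
    S4  = list(probe = 40.0, ligandDd =  8, pocketDd =  1,
               hbond = c(on, on, on, off)),
    S5  = list(probe = 46.1, ligandDd =  8, pocketDd = -3,
               hbond = c(on, on, on, on)),
    S6  = list(probe = 35.5, ligandDd =  8, pocketDd = -3,
               hbond = c(on, on, on, on)),
    S1p = list(probe = 35.5, ligandDd =  0, pocketDd =  4,
               hbond = c(off, on, off, off)),
    S4p = list(probe = 36.0, ligandDd =  0, pocketDd = -3,
               hbond = c(on, on, off, off))), jitter = jitter)
}

## solve for the ligand x-position giving the target mean-distance
## difference between the two domain atom sets
solveLigandX <- function(target, largeXYZ, smallXYZ, ligOffsets) {
  f <- function(g) {
    lig <- sweep(ligOffsets, 2L, c(g, 0, 0), "+")
    mean(crossDist(lig, smallXYZ)) - mean(crossDist(lig, largeXYZ)) - target
  }
  lo <- min(largeXYZ[, 1L]) - 5; hi <- max(smallXYZ[, 1L]) + 5
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Build a toy coordinate ensemble realizing order-parameter targets
#'
#' For each frame of \code{stateSequence}, constructs 3D coordinates whose
#' structural order parameters (probe distance, ligand displacement, pocket
#' rearrangement, hinge H-bond distances) equal the per-state targets of
#' \code{config}, then adds isotropic Gaussian jitter.  Atom groups are
#' labelled so the features module can measure everything back.
#'
#' @param stateSequence character (or factor/integer) macrostate label per
#'   frame; labels must exist in \code{config$states}.
#' @param config a \code{\link{geometryConfig}}.
#' @param seed integer seed for the jitter.
#' @return A \linkS4class{ConformationEnsemble} with groups
#'   \code{large_domain_CA}, \code{small_domain_CA}, \code{hinge},
#'   \code{ligand_heavy}, \code{probe_pair}, \code{hbond_pairs},
#'   \code{helixV}, \code{helixVI}, \code{strandJ}.
#' @export
buildPseudoStructures <- function(stateSequence, config = defaultGeometryConfig(),
                                  seed = 1L) {
  stopifnot(inherits(config, "GeometryConfig"))
  stateSequence <- as.character(stateSequence)
  unknown <- setdiff(unique(stateSequence), names(config$states))
  if (length(unknown))
    stop("states not in geometry config: ", paste(unknown, collapse = ", "))

  dOff <- domainOffsets(); pOff <- pocketOffsets()
  ligOffsets <- rbind(c(0, 0.4, 0), c(0, -0.4, 0))
  ## binding-site CAs reaching toward the inter-domain cleft, so that a
  ## ligand bound at a domain has residues of that domain within a
  ## crystal-structure-like contact cutoff
  ext <- rbind(c(6, 0.5, 0), c(6, -0.5, 0))
  nL <- nrow(dOff) + nrow(ext) + 1L  # domain CAs incl. centroid probe atom

  ## template per state (exact targets, no jitter)
  templates <- lapply(config$states, function(s) {
    domTemplate <- rbind(dOff, ext, c(0, 0, 0))
    largeXYZ <- domTemplate
    smallXYZ <- sweep(sweep(domTemplate, 2L, c(-1, 1, 1), "*"),
                      2L, c(s$probe, 0, 0), "+")
    gx <- solveLigandX(s$ligandDd, largeXYZ, smallXYZ, ligOffsets)
    ligXYZ <- sweep(ligOffsets, 2L, c(gx, 0, 0), "+")
    hingeXYZ <- cbind(s$probe / 2 + c(-1, 0, 1), 8, c(-1, 0, 1))
    ## H-bond pairs: pair j along x at y-offset 12 + 3j
    hb <- do.call(rbind, lapply(1:4, function(j)
      rbind(c(0, 12 + 3 * j, 0), c(s$hbond[j], 12 + 3 * j, 0))))
    d1 <- config$d2 + s$pocketDd
    pocketBase <- c(s$probe * 0.75, -15, 0)
    strandJ <- sweep(pOff, 2L, pocketBase + c(-config$d2, 0, 0), "+")
    helixV  <- sweep(pOff, 2L, pocketBase, "+")
    helixVI <- sweep(pOff, 2L, pocketBase + c(d1, 0, 0), "+")
    rbind(largeXYZ, smallXYZ, ligXYZ, hingeXYZ, hb, strandJ, helixV, helixVI)
  })

  nAtoms <- nrow(templates[[1L]])
  groups <- list(
    large_domain_CA = 1:nL,
    small_domain_CA = nL + 1:nL,
    probe_pair      = c(nL, 2L * nL),
    ligand_heavy    = 2L * nL + 1:2,
    hinge           = 2L * nL + 2L + 1:3,
    hbond_pairs     = 2L * nL + 5L + 1:8,
    strandJ         = 2L * nL + 13L + 1:3,
    helixV          = 2L * nL + 16L + 1:3,
    helixVI         = 2L * nL + 19L + 1:3)

  frames <- localSeed(seed, {
    lapply(stateSequence, function(st) {
      x <- templates[[st]]
      if (config$jitter > 0)
        x <- x + matrix(rnorm(length(x), sd = config$jitter), nrow(x), 3L)
      x
    })
  })
  new("ConformationEnsemble", frames = frames, atomGroups = groups,
      stateLabels = stateSequence)
}

#' Reference structures for feature-selection
#'
#' Zero-jitter single-frame ensembles of a large-domain-bound closed state
#' and a small-domain-bound closed state, used by
#' \code{\link{buildFeatureMatrix}} to select the binding-site residues
#' (both binding modes must contribute contact residues).
#'
#' @param config a \code{\link{geometryConfig}}; defaults to the 8-state
#'   geometry.
#' @param states the two state labels to realize (default \code{c("S6",
#'   "S1")}).
#' @return List of two \linkS4class{ConformationEnsemble} objects.
#' @export
defaultReferenceStructures <- function(config = NULL,
                                       states = c("S6", "S1")) {
  if (is.null(config)) config <- defaultGeometryConfig(jitter = 0)
  config$jitter <- 0
  lapply(states, function(s) buildPseudoStructures(s, config, seed = 1L))
}
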