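Package: msmfret
Title: Markov State Models, Kinetic Networks and Single-Molecule FRET
    Analysis for Ligand-Bound Protein Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and validate Markov state models of protein
    conformational dynamics from trajectory features (tICA dimensionality
    reduction, k-center microstate clustering, transition-matrix estimation,
    implied-timescale and GMRQ cross-validation diagnostics), to lump
    microstates into metastable macrostates by Perron-cluster analysis and
    derive kinetic-network quantities (stationary populations, mean first
    passage times) by Monte-Carlo propagation with closed-form oracles, to
    aggregate per-frame binding energies into population-weighted
    macrostate and ensemble binding free energies with bootstrap errors,
    and to analyse single-molecule FRET traces (Gaussian-emission hidden
    Markov models, transition density plots, full-width-half-height state
    thresholds, state populations, Gaussian mixture fits). A synthetic-data
    module generates every input class with known ground truth: reversible
    kinetic networks, multi-well Brownian-dynamics landscapes, pseudo
    structures realising structural order parameters of a two-domain
    periplasmic binding protein, FRET traces and binding-energy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
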