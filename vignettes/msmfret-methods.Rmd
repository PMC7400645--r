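---
title: "Models and methods behind msmfret"
author: "msmfret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msmfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`msmfret` implements, as one tested pipeline, the computational analyses
used to characterize the conformational dynamics of a ligand-bound
two-domain binding protein: Markov-state-model (MSM) construction and
validation from trajectory features, macrostate lumping and
kinetic-network quantities, ensemble-weighted binding-energy
aggregation, structural order parameters, and smFRET trace analysis.
All-atom MD production, Poisson–Boltzmann solvers and wet-lab protocols
are out of scope: the package consumes features, per-frame energies and
traces, and ships generators that produce all of these with known
ground truth.

# The Markov state model

The central object is a row-stochastic transition matrix $T(\Delta t)$
estimated at a lag $\Delta t$; state populations propagate as
$P(n\Delta t) = [T(\Delta t)^\top]^n P(0)$.  The modelling assumptions
are the usual ones: within-state relaxation is fast compared to
$\Delta t$, so that the jump process is Markovian at the chosen lag, and
the trajectories sample a stationary, reversible process.

**Features and tICA.** Input features are internal distances
(inter-domain Cα–Cα pairs over binding-site residues, mean
ligand-to-Cα distances, the FRET probe-pair distance), which makes the
representation rigid-motion invariant without trajectory alignment.
tICA solves the generalized eigenproblem
$C_\tau v = \lambda C_0 v$ with both covariances estimated on the pooled
time-lagged pair ensemble; in one dimension the eigenvalue therefore
reduces exactly to the empirical lag autocorrelation, which is the
identity the unit tests pin down.  A ridge of $10^{-8}\,
\mathrm{tr}(C_0)/d$ is added when $C_0$ is near-singular (with a
warning), and eigenvectors are normalized in the $C_0$ metric.

**Microstates.** Greedy max–min (Gonzalez) k-center clustering defines
microstates in tICA space; the first center is a seeded random point and
ties break to the lowest index, so clustering is deterministic given the
seed.  The greedy covering radius is within a factor 2 of optimal, a
guarantee the tests verify by exhaustive enumeration on small
instances.  States with fewer than `minCount` frames (default 15) are
removed, their frames reassigned to the nearest retained center
(represented by its center coordinates), and the model is restricted to
the largest strongly connected component of the lag-1 count graph —
propagating $T$ requires irreducibility, and the package chooses
ergodic trimming over silently renormalizing a reducible matrix.

**Estimation.** Transition counts use stride-1 sliding windows at the
lag, never across trajectory boundaries.  The default estimator
symmetrizes counts, $(C + C^\top)/2$, before row normalization: it is
deterministic, reversible by construction (real spectrum, so implied
timescales are well defined) and adequate at the package's fixture
scale.  Maximum-likelihood reversible estimation is a documented
extension, not implemented.  Sliding-window counts are correlated, which
inflates nominal count-based confidence statements; all uncertainty
reported by the package therefore comes from resampling whole
trajectories, not from counts.

**Validation.** Implied timescales $\tau_k = -\tau / \ln \mu_k(\tau)$
are reported per lag with a bootstrap over whole trajectories;
eigenvalues outside $(0,1)$ yield flagged `NA` timescales rather than
fabricated numbers.  Residence-probability checks compare $(T^n)_{ii}$
against empirical window statistics.  GMRQ shuffle-split
cross-validation (default 50 iterations, half the trajectories as
training set) scores a trained model's top eigenvectors on held-out
correlation matrices via the generalized matrix Rayleigh quotient
$\mathrm{tr}[(V^\top D V)^{-1} V^\top S V]$; the score of the trivial
one-state model is exactly 1, the score never exceeds the number of
eigenvalues summed, and the population score is bounded by the true
spectrum (variational principle).  The number of summed eigenvalues is
configurable with default 5 ("several highest" is otherwise
unspecified).

# Macrostates and kinetics

PCCA+ lumps a reversible, irreducible $T$: the top $n$ right
eigenvectors span a simplex whose vertices index the metastable sets.
The implementation uses the deterministic vertex-seeded inner-simplex
search (most-spread eigenvector rows, successive orthogonal
projection), inverts the vertex rows to get memberships, clips small
negative entries, renormalizes and crisps by maximal membership.
Reproducibility is preferred over global optimality of the crispness
objective at this scale.  Eigenvalue degeneracy at the spectral cut
(within $10^{-10}$) is an error advising a different macrostate count,
not a silent arbitrary cut.

Stationary populations and MFPTs are estimated by Monte-Carlo
propagation (default 100 trajectories; the first third of each is
discarded as equilibration, mirroring a 100 ms burn-in of 300 ms
chains).  MFPT(a→b) is defined entry-to-first-entry: each entry into
macrostate *a* starts a clock that stops at the first subsequent entry
into *b*; clocks are averaged within a trajectory, then mean ± sd are
taken across trajectories.  Passages not completed by the end of a
trajectory are dropped, which biases long MFPTs downward by roughly
MFPT/length — the acceptance experiments therefore use trajectories at
least ~50× longer than the slowest fixture MFPT, and the closed-form
check (`mfptExact`, the linear system $m = \tau + Tm$ off the target,
entry-flux weighted per `mfptExactTable`) is the reference whenever an
exact answer is needed.

# Energetics

The package consumes per-frame binding energies; it does not compute
Poisson–Boltzmann or SASA terms (those came from an external tool in
the reference workflow, and the implementable content is the weighting
statistics).  Per bootstrap iteration one record is drawn per
microstate; a macrostate's energy is the within-macrostate
population-weighted sum, the ensemble energy the global
population-weighted sum, and means ± sd are reported over 1000
iterations.  By linearity the ensemble value equals the
macrostate-population-weighted mean of macrostate values in every
iteration — an identity the tests check to $10^{-10}$.  Entropy terms
are excluded by construction.  `kdToDeltaG` uses
$\Delta G = RT \ln(K_d/1\,\mathrm{M})$ with $R = 8.314$ J mol⁻¹ K⁻¹ and
the 1 M standard state; for $K_d = 202$ nM at 291.15 K this gives
−37.3 kJ/mol.  Published equivalences that disagree with this formula
are not reproduced; the package documents the standard convention and
leaves it at that.

# smFRET analysis

Efficiency is $E = I_A/(I_A + I_D)$ with no gamma or background
correction (hooks for both are the natural extension point); frames
with non-positive total intensity are flagged and excluded.  The hidden
Markov model is Gaussian-emission Baum–Welch EM with seeded k-means
initialization, a strict non-decreasing log-likelihood check every
iteration, empty-state restarts (≤ 5) and BIC model selection over 1..6
states; idealization is Viterbi.  This is a deliberate substitution of
maximum-likelihood EM + BIC for variational-Bayes HMM software: at the
fixture noise levels the two select the same state count, and ML-EM is
deterministic given the seed.

The transition density plot dresses each idealized change point
$(E_\text{before}, E_\text{after})$ with a unit-mass isotropic 2D
Gaussian of width σ = 0.03 efficiency units (configurable; the
reference analysis states no width), so the density integrates to the
number of transitions.  Six 2D Gaussians are fitted by
Levenberg–Marquardt least squares seeded from the six largest local
maxima (fewer maxima ⇒ reduced fit, flagged).  Component coordinates
from both axes are pooled into ≤ 4 marginal state centers by
single-linkage merging at 0.05 efficiency units — six off-diagonal
blobs among four levels must map to at most four centers — and each
state's classification interval is center ± FWHH/2 with
$\mathrm{FWHH} = 2\sqrt{2\ln 2}\,\sigma$; adjacent intervals that would
overlap are truncated at center midpoints.  Populations are fractions
of frames inside each interval; the default classifies idealized
frames (each frame's fitted emission mean), while raw mode classifies
measured efficiencies — both are exposed because reference analyses
use idealized values for thresholds but raw time points for
histograms.  The 1D four-Gaussian mixture fitter is unit-agnostic
(probe-distance distributions are fitted the same way as efficiency
histograms).

# The synthetic-data module

The generators define the study conditions; every generator is a pure
function of (spec, seed).

* **Kinetic network.**  Metropolis construction: symmetric proposal
  rates (all-to-all within a macrostate at `intraRate`, per-edge rates
  between macrostates) with acceptance $\min(1, \pi_j/\pi_i)$ gives
  detailed balance exactly, so the stationary distribution — and hence
  every macrostate population — is exact by construction, and the
  spectrum is real.  The packaged eight-state fixture mirrors a
  two-domain binding network: fast opening/closing within each
  binding-site cluster, slow transit through semi-closed bridge states,
  and two slow off-pathway excursions; inter-macrostate propensities
  are kept at least ~5× below the intra rate so the eight-state
  metastability is spectrally well defined.  Populations follow the
  published constraints (the three ligand-induced closed states sum to
  24 %, the ligand-induced open state holds 4 %, each
  large-domain-bound state outweighs every small-domain-bound state);
  individual values are otherwise a documented synthetic transcription.
  Microstate weights within a macrostate are an uneven seeded Gamma(5)
  split, so population weighting in downstream modules is non-trivial.
* **Landscape.** The 2D potential is
  $V(x) = -k_BT \log \sum_i e^{d_i} N(x; c_i, s^2 I)$, i.e. minus the
  log of a Gaussian mixture: the Boltzmann density *is* the mixture, so
  well occupancies equal normalized weights and grid integration gives
  closed-form oracles.  The default eight wells sit on the (ligand
  position × opening) grid minus the unpopulated interface-open cell,
  spacing 2, width 0.5, depths $\ln p_i$ from the fixture populations;
  overdamped Langevin (Euler–Maruyama, $dt = 0.02$, friction 1,
  $k_BT = 1$) samples it, warning when the per-step noise displacement
  exceeds the narrowest well.
* **Pseudo-structures.** Toy coordinate templates realize the
  order-parameter targets exactly (probe distance by construction,
  ligand displacement by 1D root finding, pocket distances by centroid
  placement, H-bond pairs at target separations), then add isotropic
  Gaussian jitter (default 0.3 Å).  Binding-site "residues" extend
  toward the inter-domain cleft so that contact-based feature selection
  behaves like it does on real structures (each binding mode contributes
  contact residues in the corresponding reference structure).
* **FRET traces.** Hidden chains from the (Metropolis-constructed)
  four-state fixture with the published emission centers
  0.15/0.31/0.51/0.68 and populations 24/23/33/20 %; emission sd 0.06
  and the uniform 0.05 proposal are synthetic choices giving ~0.7 s
  dwells at 100 ms frames.  Emissions are clipped to [−0.2, 1.2]
  rather than [0, 1] because real traces show shot-noise excursions
  outside the unit interval.
* **Energies.** Gaussian records about macrostate means (10 per
  microstate by default, matching the reference sampling depth), with
  per-residue columns as exact fractions of each total so decomposition
  identities hold to machine precision.

What the generators do *not* emulate: non-Markovian memory,
force-field-level energetics, photophysics (bleaching, blinking,
gamma), spatial overlap between conformational states beyond Gaussian
jitter, and heterogeneity between traces.  Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every artifact of real data.

# Problem sizes and numerical choices

The test and acceptance experiments run at desk scale, chosen so the
full suite completes in a few minutes on one CPU: the landscape
recovery experiment uses 50 trajectories × 5000 steps, 300 k-center
microstates (a scaled-down analogue of the reference 750), pruning at
15 frames and an MSM lag of 20 steps; Monte-Carlo oracle checks use 50
trajectories of 10⁵ steps; the smFRET acceptance run uses 200 traces ×
1000 frames.  Tie-breaks are everywhere to the lowest index; every
stochastic step takes an explicit seed and restores the caller's RNG
state; eigenvalues are sorted by modulus, and complex eigenvalues (raw
estimation mode only) enter the timescale formula by modulus with a
flag.  Stochastic test assertions use 3-standard-error bounds, with a
Šidák-corrected simultaneous quantile when a single assertion covers
many cells at once.

# Known limitations

* The symmetrized estimator is biased for irreversible processes and
  under-weights rarely-visited states relative to ML-reversible
  estimation.
* Entry-to-entry MFPT from finite trajectories is biased downward by
  passage censoring (~MFPT/length); prefer `mfptExactTable` when the
  matrix is available.
* The TDP Gaussian fit assumes isotropic components and can merge
  overlapping blobs when state separations approach the dressing
  width.
* PCCA+ vertex seeding is deterministic but not globally optimal; for
  ill-separated spectra the lumping error is the dominant error mode.
* No gamma/background correction or photophysics modelling in the
  smFRET branch.
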