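# msmfret

Markov state models, kinetic-network analysis and single-molecule FRET
trace analysis for ligand-bound protein conformational dynamics, with a
synthetic-data module that generates every input class with known ground
truth.

## The scientific problem

Ligand-bound two-domain binding proteins (the motivating system is a
periplasmic glutamine-binding protein) are not locked in the single
closed conformation seen in crystal structures: they exchange among
several metastable states that differ in domain opening and in where the
ligand sits (large domain, small domain, or the inter-domain interface).
Characterizing that exchange requires three analyses that this package
implements as one tested pipeline:

1. **Markov state models (MSMs).** Trajectory features (inter-domain
   Cα–Cα distances, ligand–domain distances, the FRET probe-pair
   distance) are reduced by time-structure independent component
   analysis (tICA), clustered into microstates by greedy k-center,
   pruned, and summarized by a row-stochastic transition matrix
   *T*(Δt).  Long-time dynamics follow from Eq.
   *P*(*n*Δt) = [*T*(Δt)ᵀ]ⁿ *P*(0); model quality is judged by implied
   timescales τ_k = −τ / ln μ_k(τ) (with trajectory bootstrap),
   residence-probability checks, and GMRQ shuffle-split
   cross-validation.
2. **Kinetic networks.** Microstates are lumped into metastable
   macrostates by PCCA+ (Perron-cluster cluster analysis); stationary
   populations and mean first passage times (MFPTs) are computed by
   Monte-Carlo propagation of the microstate matrix, and verified
   against closed-form oracles (stationary eigenvector; the linear
   first-passage system m = τ + T m).
3. **Ensemble energetics and smFRET.**  Per-frame binding energies are
   aggregated into macrostate and ensemble binding free energies by the
   population-weighted one-record-per-microstate bootstrap (1000
   iterations), including per-residue contribution fractions and
   Kd ↔ ΔG arithmetic (ΔG = RT ln K_d at the 1 M standard state).
   smFRET traces are analysed with a Gaussian-emission hidden Markov
   model (Baum–Welch EM, BIC model selection, Viterbi idealization), a
   transition density plot (TDP) dressed with 2D Gaussians, a
   six-component 2D Gaussian fit, full-width-half-height (FWHH) state
   thresholds, and threshold populations.

Because real inputs for such a study (tens of microseconds of MD,
MM-PBSA solver output, smFRET movies) are not shippable, the
`synthetic_data` module is a first-class, tested component: reversible
Metropolis network matrices with exact stationary distributions,
Brownian-dynamics sampling of multi-well 2D landscapes whose Boltzmann
measure is known in closed form, toy 3D structures that realize the
structural order parameters exactly, four-state FRET trace generators,
and binding-energy tables with known macrostate means.

## Worked example

Four-state smFRET fixture (emission means 0.15/0.31/0.51/0.68,
stationary populations 24/23/33/20 %), analysed blind by the full
pipeline:

```r
library(msmfret)
spec   <- fixtureSmfretFig6(traceLength = 500, nTraces = 50, seed = 11)
traces <- generateFretTraces(spec)
hmm    <- fitHmm(traces, KMax = 6, seed = 12)   # BIC model selection
hmm
#> HmmFit: 4 states, logLik 23001.21, BIC -45769.51
#>   means: 0.148 0.311 0.509 0.681
thr  <- deriveThresholds(fitTdpGaussians(buildTdp(hmm), seed = 13))
thr
#> StateThresholds:
#>   E1: 0.113 - 0.184
#>   E2: 0.276 - 0.346
#>   E3: 0.474 - 0.545
#>   E4: 0.646 - 0.717
round(statePopulations(hmm, thr)$populations, 3)
#>    E1    E2    E3    E4
#> 0.242 0.230 0.318 0.209
```

BIC selects four states; the recovered emission means sit within 0.003
of the generating values and the threshold populations within ~1.5
percentage points of the generating occupancies.

Kinetic network fixture (eight macrostates: small-domain-bound S1–S3,
large-domain-bound S4–S6, off-pathway S1′/S4′):

```r
net <- fixtureNetworkFig2()
T0  <- buildNetworkMatrix(net, seed = 1)       # reversible, exact populations
kin <- mcKinetics(T0, generatorMacrostates(T0), nTraj = 100,
                  length = 10000, seed = 3, macroNames = net$macroNames)
kin
#> KineticsSummary: 8 macrostates, 100 trajectories x 10000 steps (burn-in 3333)
#>   populations: 0.119 0.039 0.078 0.180 0.161 0.298 0.073 0.052
round(mfpt(kin)[c("S1","S2","S3"), c("S1","S2","S3")] / 1000, 1)  # microseconds
#>     S1  S2  S3
#> S1 0.0 2.1 0.8
#> S2 1.1 0.0 0.6
#> S3 2.8 3.7 0.0
```

The Monte-Carlo populations match the network's construction (S6 most
populated at 30 %; the three ligand-induced closed states S1, S1′, S4′
jointly 24.4 % here), and the fast intra-cluster opening/closing MFPTs
are a few microseconds at the 30 ns lag, an order of magnitude faster
than transit between the two binding-site clusters.

`runPipeline(pipelineConfig(...))` chains all stages (network →
structures → features → tICA → k-center → pruning → MSM → PCCA+ →
kinetics → energetics → smFRET) and writes JSON/CSV artifacts plus a run
manifest.

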