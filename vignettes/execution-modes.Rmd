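---
title: "Discretizing reaction fluxes into execution modes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discretizing reaction fluxes into execution modes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmodes)
```

This vignette documents the model behind `fluxmodes`, the assumptions it
makes, the tunable parameters and their defaults, and the design decisions
taken where the method left genuine freedom. The README shows the
user-facing workflow; here the emphasis is on *why* the pieces are the way
they are.

## The dominance model and its assumptions

`fluxmodes` operates on mass-action reaction networks: every reaction's
rate is a monomial $k_j \prod_i x_i^{\alpha_{ij}}$ whose exponents equal
the reactant stoichiometries. This restriction is load-bearing. The
dominance calculus compares *individual monomial terms* of
$dx_i/dt = \sum_j M_j$ on a $\log_{10}$ scale, and a sum of monomials is
only unambiguously attributable to reactions when each reaction contributes
exactly one term per direction. Saturating rate laws (Michaelis–Menten,
Hill) bundle several elementary steps into one ratio and have no canonical
term decomposition, so the package rejects them at import
(`read_sbml()` refuses non-mass-action kinetic laws) rather than guessing
one. Enzymatic mechanisms are expressed explicitly instead, as
`E + S <-> E:S -> E + P` blocks — this is also how the bundled apoptosis
model encodes all of its catalysis steps.

Reversible reactions contribute a forward and a reverse monomial with
opposite signs for any given species. These are collapsed into a single
*net* term per reaction before dominance is assessed, each unidirectional
monomial signed by the focal species' stoichiometric coefficient in that
direction and summed. Working with net terms avoids the pathology of a
fast-equilibrating reversible pair whose two large, nearly cancelling
monomials would otherwise both look "dominant" while carrying almost no net
flux.

Dominance itself is a tropical-geometry-style discretization. Among the
strictly positive (producing) net terms $R^+$, the largest term $M_d$ is
dominant, and every term within $\rho$ orders of magnitude of it,
$\mathrm{sep}(M_d, m) = |\log_{10} M_d - \log_{10} m| < \rho$, is kept "on
par" with it. Three boundary conventions are fixed here and tested as part
of the package contract:

* **Strictness at the threshold.** A term separated by *exactly* $\rho$ is
  *not* on par: on-par is `sep < rho`, dominance of one term over another
  is `sep >= rho`. Some presentations of the par/dominance pair are
  ambiguous on this point; the strict-inequality reading is the one
  consistent with treating dominance as "more than $\rho$ orders of
  magnitude apart", and ties at the boundary then resolve toward the
  sparser (more reduced) subnetwork.
* **Zeros are excluded, not log-transformed.** A monomial that evaluates to
  exactly zero (a depleted reactant) is dropped before the log-scale
  comparison; an empty production set is a legitimate outcome and maps to
  the reserved sentinel label 0.
* **Log base 10.** $\rho$ is quoted in orders of magnitude; the default
  $\rho = 1$ means "within one decade of the largest flux".

## Subnetwork tracing, labels, and fingerprints

The dominant subnetwork for a target species is built by hierarchical
back-tracing on the bipartite species–reaction graph: find the dominant
reactions producing the target, add edges from their source reactants
(the reactants of the producing direction) to the target, then repeat from
those reactants, for `depth` iterations. Two details matter:

* **Cycles terminate.** A species already expanded within the current trace
  can still *receive* new edges but is never re-expanded. Self-amplifying
  motifs — such as the MOMP positive feedback in the apoptosis model, where
  active MOMP catalyzes its own production — would otherwise loop forever.
* **The whole frontier advances per iteration.** `depth` counts waves of
  expansion, not single species visits, so the traced pathway length is
  `depth` edges deep along every dominant branch simultaneously.

The edge set is canonicalized (sorted species-to-species pairs; reaction
identities kept as metadata but excluded from the identity of a
subnetwork) and looked up in a label registry that assigns consecutive
integers in order of first appearance. One registry should be shared across
every simulation that needs comparable labels — in particular across
wild-type and perturbed conditions of the same analysis; `run_pipeline()`
and `fingerprint_ensemble()` do this automatically. Re-running an ensemble
against the same registry is bit-exact.

A simulation's fingerprint is the label sequence over the shared time grid.
The grid is fixed across the whole ensemble (default: 100 uniform points
over the simulated horizon) precisely so that fingerprints are positionally
comparable; per-member adaptive grids would make the sequence metric
meaningless. Fingerprints are compared at full time resolution, without
run-length compression: how *long* a mode dwells in a subnetwork is signal,
not noise, and collapsing runs would discard it.

## Distance and clustering

The longest-common-subsequence distance
$d_{\mathrm{LCS}}(x, y) = |x| + |y| - 2\,\mathrm{LCS}(x, y)$ is a metric on
label sequences (identity, symmetry, and the triangle inequality are
property-tested, and the LCS kernel is verified against exhaustive
subsequence enumeration). It was chosen over Hamming-style distances for
its sensitivity to the *order* in which subnetworks appear: two
fingerprints that visit the same labels in a different order are far apart
even if their label histograms match. The $O(L^2)$ dynamic programme runs
in C++; a 150-member ensemble on a 50-point grid (11,175 pairs) is
essentially instantaneous, and the cost grows quadratically in both
ensemble size and grid length.

Three clustering routes operate on the precomputed distance matrix:

* **Agglomerative (default), average linkage** via `stats::hclust`. The
  default because it is deterministic, honors an arbitrary precomputed
  metric exactly, and needs no bandwidth-like tuning.
* **Spectral**: Gaussian affinity $\exp(-d^2 / 2\sigma^2)$ with $\sigma$
  set to the median positive distance, normalized-Laplacian embedding, and
  k-means on the row-normalized leading eigenvectors (the standard
  Ng–Jordan–Weiss construction, coded directly so that it runs on a
  precomputed distance and is reproducible under the supplied seed).
* **HDBSCAN**, implemented in-package on the distance matrix:
  core distances at `min_cluster_size` neighbors, mutual-reachability
  transform, single-linkage hierarchy, condensed tree, excess-of-mass
  extraction. Points that never join a stable cluster are *kept* as a
  reserved noise mode (id 0) rather than dropped, so mode probabilities
  still sum to 1. Duplicate fingerprints produce zero merge heights; these
  are floored at half the smallest positive height so density
  ($1/\mathrm{height}$) stays finite, and a fully degenerate all-zero
  matrix short-circuits to a single mode.

When the number of clusters is not supplied, `select_n_clusters()` scans a
candidate range and keeps the k maximizing the mean silhouette width on the
precomputed distance, breaking ties toward the smallest k and returning 1
(with a warning) for an all-zero matrix. Silhouette was chosen because it
needs nothing beyond the distance matrix already in hand; it is a
heuristic, and `n_clusters` stays exposed for analyses where the mode count
is known or posited.

Mode probabilities are the summed normalized posterior weights of the
members. Weights supplied as log-posteriors are converted by max-subtracted
exponentiation (overflow-safe softmax); absent weights default to uniform.

## The synthetic ensemble generator

Full Bayesian calibration (DREAM-family MCMC) is out of scope by design:
the package *consumes* parameter ensembles. For development, testing and
desk-scale demonstration, `ensemble_synth` provides three stand-ins:

* `sample_ensemble()` draws i.i.d. vectors from independent log-normal
  priors centered at biologically plausible rate scales — 1e-6 /s/molecule
  for bimolecular binding, 1e-3 /s for unbinding, 1 /s for catalysis —
  with a default spread of 1 decade (`log10_sd = 1`).
* `weight_by_fit()` attaches Gaussian-likelihood importance weights against
  (synthetic) observations: an importance-sampling sketch of a posterior,
  documented as such, not an MCMC replacement.
* `planted_regime_ensemble()` builds ensembles with *known* mode structure
  by multiplying selected rates of the toy bifurcation model by
  regime-specific factors and jittering members log-normally
  (`jitter_sd = 0.05` decades by default, small against the two-decade
  separation the default regimes plant). Regimes are validated at
  construction: jitter-free simulations of any two regimes must yield
  distinct fingerprints, otherwise the constructor errors.

What the generator deliberately does *not* emulate: posterior correlations
between parameters (draws are independent), multi-modal marginals,
simulation-failure regions of parameter space, and the heavy tails of real
MCMC output. Passing the planted-recovery tests therefore shows that the
discretize–distance–cluster chain is correct and stable under calibrated
noise, not that any particular biological ensemble has three modes.

## Downstream analyses: conventions

* **Time of death** is $(T_{10} + T_{90})/2$, where $T_{10}$ and $T_{90}$
  are the *first upward crossings* of 10% and 90% of the marker's
  trajectory maximum, linearly interpolated between grid points. The
  crossing convention is tested against a 10×-refined-grid recomputation;
  a flat-zero marker yields `NA`. Per-mode aggregation reports mean ± sd.
* **Peak statistics** use the first argmax as time-to-peak and signed
  percentages $100(\mathrm{pert} - \mathrm{ref})/\mathrm{ref}$; over an
  ensemble, per-member percentages are computed first and then summarized
  by median and IQR (median-of-percentages, not percentage-of-medians).
* **Bayesian mode update** after measuring a parameter value $s$:
  $P(X_i \mid s) \propto p_i X_i(s)$ with per-mode densities $X_i$
  estimated by Gaussian KDE over the members' $\log_{10}$ parameter
  values (Silverman reference bandwidth; a near-degenerate mode falls back
  to a narrow Gaussian). The update is invariant to a common rescaling of
  the densities and errors if every density is zero at $s$ — a measurement
  incompatible with all modes should fail loudly, not renormalize noise.
* **Mode classification** trains an xgboost multiclass soft-max model on
  $\log_{10}$ parameter values with a 75/25 train/test split, learning rate
  0.1, 100 rounds, `max_bin = 16`, L1/L2 regularization 1, single-threaded
  for determinism under the supplied seed. Parameter importance is reported
  by gain share.

## Numerical choices

* **Solver.** LSODA (`deSolve::lsoda`) with default `rtol = atol = 1e-6`.
  Looser tolerances (e.g. 1e-2/1e-1, adequate for trajectory plots of
  copies-per-cell models) are exposed as arguments but not defaulted:
  dominance compares *logarithms* of fluxes, and late-time solver noise at
  loose tolerance flips on-par decisions on small models.
* **Negative excursions** of the integrator are clipped to zero before
  monomial evaluation, keeping the log-scale comparisons defined; clipping
  happens at evaluation, the stored trajectory is the solver's.
* **Units** are copies per cell throughout; no volume conversions.
* **Determinism.** For fixed network, parameters, grid and tolerances,
  simulation, fingerprinting and agglomerative/HDBSCAN clustering are fully
  deterministic; spectral clustering and the classifier consume an explicit
  seed. `run_pipeline()` derives every stage's randomness from the single
  seed in its `run_config`.

## The bundled apoptosis model

`make_aearm()` encodes the abridged extrinsic apoptosis cascade as dynamic
motifs: TRAIL–receptor binding, reversible maturation of the
ligand–receptor complex into the DISC, and eight 3-parameter catalysis
blocks (initiator-caspase activation by the DISC, effector-caspase feedback
on initiator caspase, Bid truncation, tBid-dependent MOMP activation, MOMP
self-amplification, type-1 and type-2 effector-caspase activation, PARP
cleavage), for 22 species and 28 rate parameters. The species and parameter
counts, the motif structure, and the qualitative behavior (sigmoidal
snap-action MOMP onset; complete PARP cleavage at plausible-center rates)
are the constraints this reconstruction satisfies; the full reaction list
is in `?make_aearm` and can be exported with `write_model_dsl()`. Initial
abundances follow published extrinsic-apoptosis models (e.g. 1e6 PARP, 1e5
MOMP-pool, 2e4 initiator- and 1e4 effector-caspase zymogens per cell).

## Problem sizes used by the test suite

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path in well under a minute each: random-network
dominance oracles at ≤ 8 reactions and ≤ 5 species; LCS metric properties
on 1,000 random sequence triples with exhaustive verification at length
≤ 8; planted-mode recovery at 150 members × 50 grid points; aEARM
pipeline checks at 12 members × 40 grid points. Ensemble analyses scale
linearly in members for simulation and fingerprinting and quadratically
for the distance matrix; the same code paths run unchanged at larger sizes.

## Known limitations

* Mass-action kinetics only; no rule-based expansion, stochastic
  simulation, delays, or PDEs.
* Dominance is assessed on absolute production fluxes into the focal
  species; alternative normalizations (e.g. flux relative to protein
  abundance) are not implemented.
* The silhouette-based k selection inherits silhouette's bias toward
  compact, balanced clusters.
* The aEARM fixture is a structural reconstruction constrained as
  described above, suitable for method work at nominal or prior-sampled
  rates; analyses of the *calibrated* apoptosis posterior require that
  external ensemble, which is not bundled.
* The sequence metric is fixed to LCS distance; cost-weighted edit
  distances and consensus clustering are out of scope.
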