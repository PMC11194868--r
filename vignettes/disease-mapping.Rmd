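---
title: "Small-area disease mapping of childhood asthma: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping of childhood asthma: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmamap)
```

## The problem

Childhood asthma prevalence varies across small geographic areas, and that
variation is associated with area-level social deprivation. **asthmamap**
implements the standard small-area workflow for census-style area tables
(one row per area: child population, asthma count, percentage of Indigenous
residents, a socioeconomic disadvantage score and its decile):

1. exclusion rules and derived analysis variables,
2. queen-contiguity spatial weights,
3. global and local Moran statistics with Monte-Carlo pseudo p-values and
   LISA hotspot classification,
4. cluster-by-covariate cross-tabulation with chi-square tests,
5. Bayesian conditional-autoregressive (CAR) Poisson regression with a
   Leroux prior or a localised-cluster prior, compared by WAIC.

A synthetic-data generator reproduces the statistical structure the methods
assume, with known ground truth, so every stage can be validated end to end.

## Ingest and derived variables

Areas are dropped when they have fewer than 5 children aged 0–14, total
population below 200, a missing disadvantage score, or no remaining
neighbour among retained areas. The isolation rule runs after the population
filters and iterates to a fixed point, since removing one area can isolate
another; the order of those two steps is a design choice of this package.

The Indigenous percentage is dichotomised at the **median of the retained
areas** (ties inclusive in the `high` group). The median is recomputed from
the input rather than hard-coded, because the published threshold (2.08%) is
itself data-derived; on data resembling the national census the recomputed
threshold lands near that value. Disadvantage deciles map onto five
categories (1–2 most disadvantaged through 9–10 most advantaged). Prevalence
may be supplied directly (`prevalence_pct`) for hotspot-only analyses;
counts are mandatory for the regression stage.

## Spatial weights

Queen contiguity: two areas are neighbours when their boundaries share at
least one point, vertex or edge, detected with a snapping tolerance of
1e-8 coordinate units so serialisation round-off cannot split a shared
vertex. Moran and LISA statistics use row-standardised weights and the CAR
precision uses the binary matrix — the conventional pairing in GeoDa and
CARBayes practice.

## Moran statistics and pseudo p-values

The global statistic is `I = (n/S0) Σ_ij w_ij z_i z_j / Σ_i z_i²`. Its
Monte-Carlo test permutes values across areas and reports
`(r + 1)/(M + 1)`, `r` counting permuted statistics at least as extreme as
the observed one, up to numerical round-off. By default the tail is chosen
in the direction of the observed departure from `E[I] = −1/(n−1)`; note that
this direction-adaptive rule doubles the type-I rate of a fixed-tail test,
so calibration studies (and users testing specifically for positive
autocorrelation, the case of interest in disease mapping) should set
`alternative = "greater"`, under which the pseudo p-value is exactly
uniform on its attainable values.

Local statistics use `I_i = z_i Σ_j w_ij z_j` with `z` standardised by the
global mean and the population (divide-by-n) standard deviation — this
scaling makes the mean of the local statistics equal the global `I` and
affects only the scale of `I_i`, never its p-value. Per-area significance
comes from conditional permutation (area `i` held fixed, the other `n−1`
values permuted across its neighbour slots). Classification follows the
usual five-way scheme: high-high (hot spot), low-low (cold spot), high-low,
low-high, non-significant; defaults are `alpha = 0.05`, 999 conditional
permutations, and no multiple-testing correction (GeoDa-style); an optional
Benjamini–Hochberg mode is available (`adjust = "fdr"`). Values exactly at
the mean take the quadrant of their spatial lag; if the lag is also zero the
area is non-significant. For `n ≤ 8` both tests can enumerate all
permutations exactly (`exact = TRUE`), which the test suite checks against
brute-force oracles.

## The CAR Poisson models

Both models are `Y_i ~ Poisson(E_i exp(η_i))` with offset `E_i` the child
population, fitted by Metropolis-within-Gibbs (inner loops in C++, all
randomness from R's RNG so a seed reproduces chains bitwise).

**Leroux prior**: `η_i = x_i'β + φ_i` with
`φ ~ N(0, τ²[ρ(D − W) + (1 − ρ)I]^{-1})`. Full conditionals are
`φ_i | · ~ N(ρ Σ_j w_ij φ_j / (ρ d_i + 1 − ρ), τ²/(ρ d_i + 1 − ρ))`
(Metropolis step against the Poisson likelihood), `τ²` conjugate
inverse-gamma, and `ρ` a Metropolis step on (0, 1) whose exact
log-determinant uses the precomputed eigenvalues of `D − W`. `φ` is
recentred to mean zero each sweep with the mean absorbed into the
intercept. `ρ` is treated as unknown with a Uniform(0, 1) prior (it can be
fixed with `fix_rho`).

**Localised-cluster prior**: `η_i = x_i'β + λ_{Z_i} + θ_i` with at most `G`
strictly increasing cluster intercepts (order enforced by rejecting
violating proposals), iid `θ_i ~ N(0, σ²)`, and class labels updated by
discrete Gibbs under the penalty prior
`f(Z_i = g | δ) ∝ exp(−δ(g − G*)²)`, `G* = (G+1)/2`, `δ ~ Uniform(1, 10)`.
The penalty form is the one used in the localised-CAR literature; only the
δ prior is fixed by convention, so the concrete penalty is a documented
design choice of this package. The design intercept is dropped — the
cluster intercepts absorb the overall level — and `θ` is recentred with its
mean moved into all `λ_g`, preserving the ordering. Empty classes are legal
(`G` is a maximum).

Priors elsewhere: `β ~ N(0, 10⁵)` per coefficient (weakly informative,
the common disease-mapping default; the variance is tunable via
`prior_beta_var`), variance parameters `~ InverseGamma(1, 0.01)`, i.e.
density ∝ x^(−2) exp(−0.01/x).

### Numerical and sampler choices

* Proposal scales are auto-tuned during burn-in only (every 100 sweeps,
  targeting ≈45% acceptance for scalar updates), so the post-burn-in chain
  is a fixed-kernel Markov chain.
* The penalty parameter δ is initialised at the bottom of its support: a
  mid-support start weights outer classes by `exp(−4δ)` before the
  likelihood has any say, which can empty them irrecoverably.
* λ is initialised at quantiles of the raw log rates and `Z` at the nearest
  initial λ; β at the Poisson GLM estimate.
* WAIC uses the retained-draw pointwise log-likelihood with a stable
  log-mean-exp (`lppd`), `p_waic` as the pointwise variance, and
  `waic = −2(lppd − p_waic)`.
* The Geweke diagnostic compares the first 10% with the last 50% of a
  chain, segment-mean standard errors estimated by batch means
  (`⌊√m⌋` batches).
* Defaults are 30,000 iterations, 10,000 burn-in, thinning 10 — the routine
  validation scale used throughout the package's tests and scripts; full
  analyses use 300,000/100,000 via the same arguments.
* Prior-only runs (`prior_only = TRUE`) switch the likelihood off to check
  the sampler against its own priors. φ (and θ) are then drawn exactly by
  Cholesky factorisation of the Leroux precision — with no likelihood this
  *is* the full conditional — which mixes far better than the Metropolis
  sweep; the Metropolis sweep itself is validated separately
  (`phi_method = "mh"`) against the closed-form `N(0, Q^{-1})` joint on a
  path graph.

## The synthetic generator

`simulate_covariates()` emulates the national SA2-level census table:

* child population: truncated gamma, mean 1,991, SD 1,228, range 10–7,889;
* total population: about 5.5 times the child population;
* disadvantage score: a Leroux field (ρ = 0.97) rescaled exactly to mean
  999, SD 82.5, so the score itself is strongly spatially autocorrelated,
  as area deprivation is nationally; deciles are rank-derived;
* Indigenous percentage: Gaussian copula over a second Leroux field with a
  lognormal marginal, median 2.08 and log-SD 1.19 (the published table
  fixes only the median, mean/SD and maximum, not the family; a lognormal
  matches the heavy right skew and is capped at 99.9%).

`simulate_counts()` attaches `Y_i ~ Poisson(E_i exp(x_i'β + φ_i))`; the
default β encode baseline prevalence 6.27% and prevalence ratios
(0.99, 1.01, 1.04, 1.10; 1.13) across the disadvantage categories and the
Indigenous dichotomy. Counts are not truncated: zero counts are legal, as
in the national data whose prevalence range starts at 0.

`simulate_asthma_dataset()` combines the two with a Leroux surface at
ρ = 0.98, τ² = 0.16, chosen so the simulated prevalence surface matches the
national analysis on both calibration axes at a 30 × 30 lattice: standard
deviation near 1.95 percentage points and strong positive global
autocorrelation (Moran's I ≈ 0.4–0.5, the regime of the published 0.60).
Because `exp(φ)` has mean above one, the wrapper calibrates the intercept
against the realised field so the expected overall prevalence equals the
target exactly.

`sample_localised_structure()` grows `G` spatially contiguous classes from
random seed areas by neighbour accretion and pairs them with strictly
increasing intercepts. For the model-comparison experiments the package
uses a total log-risk span of 1.6 across three blocks — cluster prevalences
from roughly 2.8% to 14%, consistent with the observed national range
(0–16.5%). With much smaller spans the two model classes fit a blocky
surface almost equally well and WAIC cannot separate them; well-separated
regimes are the setting the localised prior exists for.

**What the generator does not emulate**: real SA2 polygons (a unit-square
lattice preserves the contiguity statistics the methods depend on), age/sex
structure within areas, reporting bias in parent-reported asthma, and any
covariate the census does not provide. Passing tests therefore demonstrate
the correctness and calibration of the machinery on data satisfying the
model's assumptions — not that the model assumptions hold for any
particular real dataset.

## Problem sizes used in validation

The test-suite and acceptance experiments run at simulation scales chosen as
the smallest that make each property measurable: exact permutation oracles
at n ≤ 8; calibration of the Monte-Carlo test over 500 iid fields on a 6 × 6
lattice; prior recovery on 3 × 3 lattices with 2,000 retained draws;
coefficient recovery over twenty 20 × 20 lattices; WAIC model comparison
over ten 15 × 15 lattices; the full pipeline on 8 × 8 fixtures. Published
national-scale quantities (overall prevalence 6.27%, Moran's I 0.60, the
WAIC values near 18,600–18,760, and the Table of prevalence ratios) depend
on the real census extract and serve here as generator-calibration anchors,
not as reproduction targets.

## A worked run

```{r example, eval = FALSE}
g <- generate_lattice(30, 30)
syn <- simulate_asthma_dataset(g, seed = 1)
fix <- write_fixture(syn$table, g, tempfile("asthma-"), truth = syn$truth)

cfg <- pipeline_config(fix[["table"]], fix[["geometry"]],
                       outdir = tempfile("report-"), seed = 1,
                       models = c("leroux", "localised:3", "localised:5"))
bundle <- run_pipeline(cfg)
bundle
summary(bundle$fits[[bundle$best_model]])
```

## Known limitations

* The localised model's label posterior is multimodal; at weak cluster
  separation WAIC legitimately prefers the smoother Leroux fit, and label
  flicker at cluster boundaries inflates `p_waic`.
* The direction-adaptive pseudo p-value doubles the nominal size when used
  as an automatic test; fix the alternative when calibration matters.
* `queen_contiguity()` detects shared vertices and vertices lying on
  edges; exotic geometries whose boundaries cross without any vertex
  involvement are out of scope.
* Dense eigendecomposition of `D − W` (for the ρ update) is cubic in the
  number of areas; at a few thousand areas it is a one-off cost of seconds,
  but far larger maps would want a sparse approach.
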