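# asthmamap

Small-area spatial epidemiology of childhood asthma prevalence in R.

Census-style area tables report, for each small area, the number of
children, the number ever diagnosed with asthma, the percentage of
Indigenous residents, and a socioeconomic disadvantage score with its
decile. **asthmamap** implements the full disease-mapping workflow for such
tables — for spatial epidemiologists and health-geography analysts who want
the standard exploratory and model-based pipeline in one tested package:

* **Exploratory spatial analysis** — queen-contiguity weights, global
  Moran's *I* with Monte-Carlo pseudo p-values
  (`(r + 1)/(M + 1)` over `M` permutations), local Moran (LISA) statistics
  with conditional-permutation p-values, and the five-way hotspot
  classification (high-high, low-low, high-low, low-high,
  non-significant).
* **Cluster–covariate association** — cross-tabulation of hot and cold
  spots against sociodemographic groups with Pearson chi-square tests.
* **Bayesian spatial regression** — CAR Poisson models
  `Y_i ~ Poisson(E_i exp(η_i))` with offset `E_i` (child population) and
  either the **Leroux prior**, `φ ~ N(0, τ²[ρ(D − W) + (1 − ρ)I]^{-1})`,
  or a **localised-cluster prior**,
  `η_i = x_i'β + λ_{Z_i} + θ_i` with ordered cluster intercepts
  `λ_1 < … < λ_G`, iid `θ_i ~ N(0, σ²)` and a penalised allocation prior
  `f(Z_i = g | δ) ∝ exp(−δ(g − G*)²)`, `δ ~ U(1, 10)`. Fitted by
  Metropolis-within-Gibbs (C++ inner loops), with WAIC model comparison,
  Geweke diagnostics, and prevalence-ratio (`PR = exp(β)`) summaries with
  95% credible intervals.
* **Synthetic data with known truth** — a generator calibrated to the
  national 2021 census SA2-level descriptives (child populations, a
  spatially smooth disadvantage score with mean 999 and SD 82.5, a
  right-skewed Indigenous percentage with median 2.08, prevalence surfaces
  with mean 6.27%, SD ≈ 1.95 and strong positive autocorrelation), used to
  validate every stage by parameter recovery.
* **A seeded pipeline** — `run_pipeline()` orchestrates ingest →
  exclusions → weights → ESDA → cross-tabs → CAR models → WAIC comparison
  and writes a reproducible report (CSV/JSON/GeoJSON); a thin CLI lives at
  `inst/scripts/run-pipeline.R`.

## A worked example

```r
library(asthmamap)

g   <- generate_lattice(30, 30)               # 900 synthetic areas
syn <- simulate_asthma_dataset(g, seed = 1)   # table + generating truth

w_rs <- build_weights(g, "row_standardised")
moran_mc(syn$table$prevalence_pct, w_rs, seed = 2)
#> Moran's I Monte-Carlo test (999 permutations)
#>   I = 0.3817  (expectation -0.001112)
#>   pseudo p = 0.001  [directional]
```

The prevalence surface is strongly spatially autocorrelated — areas
resemble their neighbours far beyond chance (the smallest attainable
pseudo p at 999 permutations). Classify the areas and cross-tabulate the
clusters against disadvantage:

```r
lisa <- classify_lisa(local_moran(syn$table$prevalence_pct, w_rs, seed = 2))
chi_square_test(crosstab_clusters(lisa, syn$table$seifa_category))
#> Cluster x group cross-tabulation
#>                     cluster
#> group                cold_spot  hot_spot
#>   most_advantaged    49 (38.3%) 10 (8.7%)
#>   advantaged         31 (24.2%) 16 (13.9%)
#>   medium             20 (15.6%) 23 (20.0%)
#>   disadvantaged      18 (14.1%) 27 (23.5%)
#>   most_disadvantaged 10 (7.8%)  39 (33.9%)
#> Column totals: cold_spot = 128, hot_spot = 115
#> Chi-square = 49.1848, df = 4, p < 0.001
```

Hot spots concentrate in disadvantaged areas (33.9% of hot spots in the
most disadvantaged fifth versus 7.8% of cold spots). The spatial model
quantifies the association while borrowing strength across neighbours:

```r
fit <- fit_car_leroux(syn$table, build_weights(g, "binary"), seed = 3)
summary(fit)
#> Bayesian CAR Poisson fit (Leroux prior)
#>   areas: 900, retained draws: 2000 (30000 iterations, 10000 burn-in, thin 10)
#>   acceptance rates: beta = 0.45, phi = 0.45, rho = 0.45
#>
#> Prevalence ratios (posterior median, 95% CrI):
#>                          variable   PR         CrI geweke_z
#>     seifa_categorymost_advantaged 1.00 (reference)
#>          seifa_categoryadvantaged 0.99 (0.96-1.04)    -0.19
#>              seifa_categorymedium 1.03 (0.99-1.08)     1.09
#>       seifa_categorydisadvantaged 1.03 (0.98-1.07)     0.38
#>  seifa_categorymost_disadvantaged 1.12 (1.07-1.18)    -0.86
#>               indigenous_grouplow 1.00 (reference)
#>              indigenous_grouphigh 1.13 (1.09-1.17)    -0.07
#>
#> Variance parameters (posterior medians): tau2 = 0.1585, rho = 0.8806
#> WAIC = 7250.85  (lppd = -3224.99, p_waic = 400.44)
```

The credible intervals recover the generating coefficients (the data were
simulated with PR 1.10 for the most disadvantaged category and 1.13 for
high Indigenous density): children in the most disadvantaged areas have a
12% (7–18%) higher asthma prevalence than in the most advantaged areas,
and areas with high Indigenous density a 13% (9–17%) higher prevalence.
`fit_car_localised(..., G = 5)` fits the cluster model on the same data and
`compute_waic()` compares the two.

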