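# stemspat

Spatial pattern analysis of rainforest stem maps collected along long,
narrow inventory transects.

## The problem

In many Central African rainforests the canopy is dominated by
light-demanding trees, and competing explanations leave different spatial
fingerprints on a stem map:

* **Disturbance cohorts** — trees that recolonized large past clearings in
  pulses should be *aggregated*, and stems that settled together should have
  similar diameters: positive spatial autocorrelation of dbh at short
  distances.
* **Random placement** — if abundance reflects a slow region-wide process
  (e.g. drought adaptation), patterns should be indistinguishable from
  complete spatial randomness (CSR), with no diameter structure.
* **Environmental filtering** — species tracking micro-habitat should have
  their subplot abundances explained by altitude, slope, topography and
  distance to watercourses in a constrained ordination.

`stemspat` provides the three instruments that separate these signatures,
for ecologists working with transect-based forest inventories:

1. **Pair correlation function** `g(r)` (and Ripley's `K`) with translation
   edge correction pooled over transect rectangles, CSR Monte-Carlo
   envelopes (`g(r) = K'(r)/(2πr)`; under CSR `g = 1`, `K = πr²`), and
   classification of each pattern as aggregated / random / regular / mixed
   with an aggregation extent.
2. **Moran correlograms of dbh** over distance classes `(c_lo, c_hi]`,

   `I(c) = N/Σw_ij · Σ_{i≠j} w_ij (m_i − m̄)(m_j − m̄) / Σ_i (m_i − m̄)²`,

   an **intertype** two-species variant
   `I12(c) = Σ w_ij z1_i z2_j / (σ1 σ2 Σ w_ij)` (each species standardized
   by its own mean and divisor-N standard deviation), mark-permutation
   envelopes, and a Mantel permutation summary of diameter similarity
   against log distance.
3. **Canonical correspondence analysis** built from the chi-square
   standardized matrix `Q = D_r^{−1/2}(P − rc')D_c^{−1/2}` projected onto
   the environmental predictors in the row-weighted metric, with
   permutation pseudo-F tests (model / marginal / axes), backward
   elimination by a deviance-style information criterion, per-variable
   variance shares, and with/without-reference-species comparisons.

A **synthetic-forest generator** emulates the sampling design (eight 50 m
wide transects, 5–8 km long, ~450 m apart, 25 m × 50 m subplots) and
produces communities with each signature built in — Thomas cluster processes
with even-aged cohort diameters, CSR with iid diameters, and a water-affine
shade-tolerant reference species — so every statistic is testable against
known truth. `run_study()` chains the whole workflow into one reproducible,
seeded report.

## Worked example

Generate a disturbance-cohort community in a 60 ha desk-scale window and ask
whether the dominant short-lived pioneer shows the cohort signature:

```r
library(stemspat)

w   <- transect_window(rep(3000, 4))            # 4 transects x 3000 m, 60 ha
com <- gen_community(scenario_preset("h1", w, seed = 5))
com$stems
#> Stem table: 548 stems, 5 species, guilds: SLP, LLP, NPLD, STS

s1 <- com$stems[com$stems$species == "MUSCE", ]
csr_envelope(s1[, c("x", "y")], w, seq(10, 200, 10), n_sim = 100, seed = 42)
#> PCF CSR envelope: n = 106, 100 sims, 95% level
#>   classification: aggregated (extent 50 m)

cg <- moran_analysis(s1[, c("x", "y")], s1$dbh,
                     distance_bins(seq(0, 500, 100)), n_perm = 999, seed = 42)
as.data.frame(cg)[1:2, c("lo", "hi", "I", "env_lo", "env_hi", "significant")]
#>    lo  hi      I env_lo env_hi significant
#> 1   0 100 0.7304 -0.104 0.1143        TRUE
#> 2 100 200 0.2982 -0.181 0.1646        TRUE
attr(cg, "mantel_r"); attr(cg, "mantel_p")
#> [1] -0.2025445
#> [1] 0.001
```

The pattern is aggregated and diameters of stems within 100 m are far more
similar than chance (`I = 0.73` against an upper null bound of `0.11`);
similarity decays with distance (Mantel `r = −0.20`, `p = 0.001`) — the
even-aged-patch signature the cohort scenario builds in.

The environmental-filtering scenario instead puts the signal in the
ordination:

```r
com3 <- gen_community(scenario_preset("h3", w, seed = 5))
Y <- tabulate_abundance(com3$stems, make_subplots(w), "species")
f <- fit_cca(Y, com3$env)
f
#> CCA: 353 sites x 5 species, 5 constraint df
#>   total inertia 2.3380, constrained 0.3898 (16.67%)
variance_decomposition(f)
#>           term df chi_square share_raw_pct share_norm_pct
#> 1    slope_pct  1    0.00431          1.11           1.17
#> 2 dist_water_m  1    0.32609         83.66          88.23
#> 3   altitude_m  1    0.01472          3.78           3.98
#> 4   topography  2    0.02445          6.27           6.62

cmp <- compare_with_without(Y, com3$env, "GILBE")
round(100 * c(with = cmp$proportion_with, without = cmp$proportion_without), 2)
#>    with without
#>   16.67    1.24
```

Distance to water carries ~84% of the explained inertia, and removing the
single water-affine reference species collapses the environmentally
explained fraction from 16.7% to 1.2% — the whole association hangs on that
one species.

See `vignettes/spatial-methods.Rmd` for the estimators, permutation schemes,
generator assumptions and numerical choices.

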