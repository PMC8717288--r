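---
title: "Spatial pattern analysis of transect stem maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial pattern analysis of transect stem maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemspat)
```

# The scientific problem

Light-demanding canopy trees dominate many Central African rainforests, and
three processes could have put them where they stand today:

* **H1 — disturbance cohorts.** Large past clearings (e.g. abandoned
  slash-and-burn farmland) were recolonized in pulses. Survivors of one pulse
  are spatially clumped and of similar age, hence of similar stem diameter:
  the pattern should be *aggregated* and the diameters *positively
  autocorrelated* at short distances.
* **H2 — random placement.** If abundance reflects a slow, region-wide
  process (e.g. drought adaptation through deciduousness), there is no reason
  for clumping: the pattern should be indistinguishable from complete spatial
  randomness (CSR) and diameters spatially unstructured.
* **H3 — environmental filtering.** If species track micro-habitat (altitude,
  slope, topography, distance to watercourses), their abundance across
  subplots should be explained by those variables in a constrained
  ordination, and patterns may be aggregated without diameter structure.

`stemspat` implements the three statistical instruments that separate these
signatures on stem maps collected along long, narrow inventory transects —
the pair correlation function with CSR Monte-Carlo envelopes, distance-class
Moran correlograms of diameter (within one species and between two species),
and canonical correspondence analysis with permutation tests — plus a
synthetic-forest generator that produces datasets with each signature built
in, so every statistic can be validated against known truth.

# Data model and sampling geometry

The observation window is a union of axis-aligned rectangles, one per
transect (`transect_window()`): 50 m wide bands whose baselines are ~450 m
apart in a shared metric frame. The default survey geometry
(`yangambi_window()`) has eight parallel transects of 5–8 km whose lengths
sum to 50,125 m, so the 25 m × 50 m subplot grid (`make_subplots()`) has
exactly 2005 cells of 0.125 ha and the window covers 250.625 ha.

A stem map (`stem_table()`) is one row per tree: coordinates in metres,
species code, regeneration guild (SLP = short-lived pioneer, LLP = long-lived
pioneer, NPLD = non-pioneer light demander, STS = shade tolerant) and dbh
(stem diameter at 1.30 m, cm). Validation enforces the 10 cm survey
threshold, window membership, and known guild codes; `read_stem_map()`
rejects sub-threshold rows and reports their count rather than failing.

Two conventions worth stating explicitly:

* Subplot membership uses half-open intervals `[lo, hi)` on both axes, so a
  stem on a subplot boundary belongs to exactly one subplot and abundance
  tabulation conserves the stem count exactly.
* Species-level analyses are restricted to species with ≥ 50 individuals
  (`filter_species()`); guild-level diameter analyses use dbh divided by the
  species mean (`standardize_dbh_by_species()`). Division (rather than
  z-scoring) removes interspecific differences in growth rate and maximum
  size while keeping each species' relative dispersion; the intertype
  statistic below standardizes by species standard deviations where that
  matters.

# Pair correlation function and CSR envelopes

`g(r)` is the density of point pairs at separation `r` relative to the CSR
expectation: `g > 1` means aggregation, `g < 1` regularity, and under CSR
`g = 1` (equivalently, Ripley's `K(r) = πr²`; `g` is the derivative form
`K'(r)/(2πr)`).

**Estimator.** `pcf()` uses the kernel estimator with an Epanechnikov kernel
and translation edge correction, which is exact for rectangular windows and
the standard choice for elongated plots:

$$\hat g(r) = \frac{1}{2\pi r\, \hat\lambda^2 |W|} \sum_{i \ne j}
  \frac{|W|\, k_h(r - d_{ij})}{(L_x - |dx_{ij}|)(L_y - |dy_{ij}|)}$$

with `λ̂² = n(n−1)/|W|²`. `ripley_K()` is the indicator-kernel analogue. Only
within-transect pairs are observable (the gaps between transects are outside
the window), so pair sums pool across transects as a ratio of sums: pooled
weighted pair sums over `Σ_t n_t(n_t−1)/|W_t|`. For a single rectangle this
reduces to the standard translation-corrected estimator, and it remains
approximately unbiased under CSR for any transect set.

**Bandwidth.** Stoyan's rule of thumb `h = 0.15/√λ̂` (metres), overridable.
With typical densities of 2–25 trees/ha this gives h ≈ 3–11 m.

**Envelopes.** `csr_envelope()` simulates `n_sim = 100` CSR patterns with the
observed point count in the same window (counts multinomial over rectangles
by area) and takes pointwise `α/2` and `1−α/2` quantiles of the simulated
`ĝ`. Quantiles use type 6 (`p(n+1)` plotting positions), the Monte-Carlo
envelope convention: the measured pointwise exceedance on CSR data is then
≈ 5% at the nominal 95% level, where ordinary type-7 interpolation gives
≈ 6.5–7%.

**Classification.** A pattern is *aggregated* if `ĝ` exceeds the upper
envelope on a contiguous run of grid points starting at the smallest scanned
distance, *regular* if it falls below the lower envelope there, *random* if
it stays inside everywhere, *mixed* otherwise. Two refinements keep the
family-wise false-alarm rate of this pointwise scan near the nominal level:

1. a run counts only if it spans at least `min_run = 2` grid points, and
2. only if it spans more than the kernel support (`2h`) in distance —
   adjacent grid values closer than the bandwidth share kernel mass, so a
   short run at the kernel scale carries no more evidence than an isolated
   point.

Without these rules a CSR pattern scanned at 20–30 grid points would be
called non-random 20–40% of the time, which would make the "random"
label useless in practice. Genuine aggregation produces long runs (5+
points in the cohort scenarios below) and is unaffected. The *aggregation
extent* is the upper end of the initial significant run — "aggregates up to
X m".

**Guard.** Transects are 50 m wide, so beyond `r ≈ 25` m the pattern is
effectively one-dimensional along the transect; estimates remain valid
(the translation correction accounts for the geometry) but lose the
isotropic interpretation, and `pcf()` warns once when the grid extends past
the half-width.

# Moran correlograms of stem diameter

For distance classes `(c_lo, c_hi]` — default upper edges 100, 200, …,
4000 m — `moran_correlogram()` computes

$$I(c) = \frac{N}{\sum w_{ij}} \cdot
  \frac{\sum_{i \ne j} w_{ij}(m_i - \bar m)(m_j - \bar m)}
       {\sum_i (m_i - \bar m)^2},$$

`w_ij = 1` when the pair distance falls in the class. `I(c) > 0` at short
distances is the cohort signature: nearby stems more similar in diameter
than random pairs. The randomization expectation is `−1/(N−1)`; the
two-point instance returns exactly −1.

The **intertype** variant (`intertype_moran()`) compares two species:

$$I_{12}(c) = \frac{\sum_{i \in 1}\sum_{j \in 2} w_{ij}\, z_{1i} z_{2j}}
  {\sigma_1 \sigma_2 \sum w_{ij}},$$

with each species centred by its own mean and scaled by its own standard
deviation. The σ's use divisor `N` (the maximum-likelihood form): with that
choice a species compared against an exact copy of itself reproduces the
within-species `I(c)` on every distance class to machine precision
(coincident self-pairs have distance 0 and fall in no `(lo, hi]` class),
which the test suite verifies across bin configurations. Both statistics
are invariant to positive affine transformations of the marks.

**Significance.** `mark_permutation_envelope()` permutes marks over fixed
locations (999 draws, pointwise type-6 quantiles); the intertype version
permutes each species' marks independently. Classes with fewer than 30 pairs
are flagged `low_support` — the variance of `I` explodes there. As a
correlogram-wide summary, `dbh_mantel()` runs a Mantel permutation test
between the pairwise similarity matrix `z_i z_j` and `ln(d_ij)` (coincident
points get a 0.5 m offset before the log, with a warning); a negative
correlation means diameter similarity decays with distance. Mantel
significance is two-sided on `|r|` with `p = (1 + exceedances)/(1 + n_perm)`.

# Canonical correspondence analysis

`fit_cca()` implements CCA directly. With `P = Y/y_{++}`, row masses `r` and
column masses `c`, the chi-square standardized matrix is
`Q = D_r^{−1/2}(P − rc')D_c^{−1/2}`; its total sum of squares is the total
inertia of the correspondence analysis. The predictors (numeric variables
as-is; topography expanded to three indicator contrasts against the
reference level "flat") are weighted-centred and the constrained part is the
projection of `Q` onto their span in the row-weighted metric. Singular
values of the projection give the constrained eigenvalues; the residual
gives the unconstrained axes. Constrained + residual inertia = total inertia
is an exact identity of the projection and is asserted to 1e−8 on every fit.
Rank-deficient (collinear) designs fall back to the least-norm span with a
warning; empty rows and species columns are dropped with counts recorded.
Species scores are scaled by the singular values ("scaling 2", affecting
plots only); site scores come in linear-combination and weighted-average
forms; biplot scores are weighted correlations of predictors with the
constrained axes.

**Permutation tests** (`anova_cca()`): the model test permutes predictor
rows against the fixed community; pseudo-F is
`(CI/q)/(RI/(n−1−q))` with `q` the constraint rank. Marginal tests for each
term refit the reduced model and permute rows of the reduced-model residual
of `Q` (weights held fixed) — the standard reduced-model residual scheme.
Sequential axis tests compare each constrained eigenvalue against its
permutation distribution from the model-test permutations. Null calibration
(predictors independent of the community by construction) gives approximately
uniform p-values for both scopes, and the pseudo-F is invariant to joint
relabeling of sites.

**Backward elimination** (`backward_select()`) uses the deviance-style
criterion `n·ln(RI/n) + 2(1+q)`. There is no canonical AIC for CCA; this
analog penalizes constraint rank like parameters and reduces selection to a
transparent, auditable trace (exposed in the result). On pure-noise
predictors the procedure returns the intercept-only model in ≳ 95% of
replicates for community tables of realistic richness (the retention
probability of one noise df behaves like `P(χ²_{m−1} > 2(m−1))`, so very
species-poor tables are more permissive); a genuine gradient survives
elimination essentially always at the simulated effect sizes.

**Variance shares** (`variance_decomposition()`): each term's marginal
chi-square (inertia added holding all other terms) as a share of the
constrained inertia, raw and normalized to 100%. With predictors orthogonal
in the row-weight metric the raw shares sum to exactly 100%.
`compare_with_without()` refits after removing a focal species column —
the design for asking how much of the environment–community association one
water-affine reference species carries.

# The synthetic forest

Every generator is a pure function of (parameters, seed); sub-seeds are
derived per species and stage by hashing, so adding a species never shifts
another's randomness.

* `sim_poisson()` — homogeneous Poisson (CSR): counts Poisson(intensity ×
  area) per rectangle, uniform positions. The H2 template.
* `sim_thomas()` — Thomas cluster process: Poisson parents in rectangles
  dilated by `4σ` (edge deficit < 10⁻³ of offspring mass), Poisson(μ)
  offspring per parent, isotropic Gaussian(σ) dispersal, clipped to the
  window. Its closed form `g(r) = 1 + exp(−r²/4σ²)/(4πκσ²)` is the
  simulator oracle used in the tests. The H1 template for short-lived
  pioneers.
* `assign_cohort_dbh()` — even-aged patches: each point joins its nearest
  patch centre (the Thomas parents), the patch age sets a cohort mean
  diameter through a saturating growth curve `dmax(1 − e^{−k·age})`
  (defaults `dmax = 150` cm, `k = 0.015`/yr — only the cohort similarity
  matters for the tests, not the growth model), plus Gaussian noise (5 cm),
  floored at the 10 cm threshold. Patch ages are uniform on 20–150 yr,
  spanning recent clearings to century-old regrowth.
* `sim_water_affine()` — inhomogeneous Poisson by thinning with retention
  `exp(−dist_water/decay)`: the shade-tolerant reference species hugging the
  watercourses. With rivers every 800 m and `decay = 40` m, ~90% of its
  stems fall in the lowest distance-to-water quartile.
* `gen_environment()` — subplot altitude = linear trend + smooth sinusoidal
  noise (random phases), optionally carved by Gaussian valleys at the river
  lines (making altitude and distance-to-water positively correlated, as in
  a dissected landscape); slope = |∇altitude| in percent; rivers are
  vertical lines at fixed x positions — adequate for distance gradients
  without real hydrology; topography is deterministic from slope and
  altitude quartiles (steep → "slope", lowest quartile → "shallow", highest
  → "crest", else "flat"). A flat configuration yields slope 0 and all-flat
  topography exactly.

`scenario_preset("h1" | "h2" | "h3")` bundles five species (two SLP, one
LLP, one NPLD, one STS reference) with per-hectare rates of the same order
as the field densities (SLP ≈ 2.25/ha from κ = 0.15 parents/ha × μ = 15,
σ = 50 m; others 1.6–2/ha), and `gen_community()` realizes a full stem map +
environment table + truth record.

**What the generator does and does not emulate.** It reproduces the transect
geometry, guild structure, clustered vs random placement, cohort diameter
structure, and environment-tied intensity — the features the statistics
consume. It does not model demographic dynamics (mortality, recruitment,
competitive thinning), dispersal kernels, within-patch age mixtures, or
measurement error in coordinates; passing recovery tests therefore shows the
estimators detect the designed signatures at realistic sizes, not that real
forests contain them.

# Problem sizes and numerical choices

Validation and recovery runs use a desk-scale window of 4 transects × 3000 m
(60 ha) with the same per-hectare process rates as the presets — only the
window is scaled. At 60 ha each SLP species has ≈ 9 expected patches
(Poisson; fewer than 3 patches has probability ≈ 0.006) and ≈ 135 stems, so
the cohort and aggregation signals exist in essentially every realization
while a full scenario × 50 seed sweep stays within minutes. The PCF is
scanned at 10–200 m in 10 m steps (clusters have σ = 50 m, so the signal
lives well inside 200 m), Moran classes at (0,100] … (400,500]. Under these
conditions the recovery rates are ≈ 94–100% for H1 aggregation and
short-range diameter autocorrelation, ≈ 96–100% for H2 randomness and
non-significance, and ≈ 100% for H3's distance-to-water dominating the CCA
decomposition.

Other numerical choices: distance classes are half-open `(lo, hi]`;
coincident points contribute to no Moran class (distance 0) and trigger the
0.5 m log-offset in the Mantel matrix; constraint rank uses a relative
singular-value tolerance of 1e−9; constrained eigenvalues below 1e−8 of the
leading one are treated as numerically zero; all permutation p-values use
the `(1 + exceedances)/(1 + n_perm)` convention so p is never 0.

# Known limitations

* The PCF assumes a homogeneous intensity within the window; no
  inhomogeneous or anisotropic variants are provided, so for strongly
  gradient-driven species (the H3 reference) aggregation and habitat
  association are deliberately read from different instruments.
* Exact numerical replication of any particular field study's curves is not
  claimed: published analyses rarely state their edge correction, bandwidth,
  envelope convention or CCA selection criterion, and those choices move the
  numbers at the few-percent level.
* The Mantel summary builds dense `n × n` matrices; units larger than
  `max_mantel_n` (default 2000) report `NA` rather than exhausting memory.
* The AIC analog for CCA is one defensible choice among several; the
  elimination trace is exposed precisely so users can audit it.

# The full pipeline

```{r, eval = FALSE}
w <- transect_window(rep(3000, 4))
com <- gen_community(scenario_preset("h1", w, seed = 5))
cfg <- run_config(min_n = 50, r_grid = seq(10, 200, 10),
                  bin_edges = seq(0, 500, 100), n_sim = 100, n_perm = 999,
                  seed = 11)
report <- run_study(com$stems, com$env, w, cfg)
print(report)
write_study_report(report, "report")
```

`run_study()` executes the stages in the field-study order — filter, PCF +
envelope per guild and per retained species, Moran correlograms (computed
for every unit but flagged for interpretation only where the pattern is
aggregated, following the field convention), intertype tests for all
short-lived-pioneer pairs, and the four-way CCA (guild/species × with/
without the reference species). Per-unit failures are recorded and the run
continues; the same configuration and seed reproduce the report
byte-for-byte.
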