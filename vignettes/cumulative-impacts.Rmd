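---
title: "Methods: cumulative environmental and occupational impact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative environmental and occupational impact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumimpact)
```

## Scope

`cumimpact` implements a census-tract level analysis of cumulative
environmental and occupational exposure burdens and their relationship with
marginalized communities, historical redlining, and composite
environmental-justice (EJ) screening scores. The analysis unit is a tract
record carrying six occupational exposure indicators (five day-count
frequencies per standard 250-day work-year — chemical contaminants,
hazardous equipment, hazardous conditions, disease/infection, physical
proximity to other workers — and a count of workers exposed to hazardous
noise), seven environmental exposure indicators (PM2.5, diesel PM, ozone,
air toxics cancer risk, respiratory hazard index, traffic volume, and a
transportation-noise indicator), demographic percentages, and optional
1930s Home Owners' Loan Corporation (HOLC) redlining fields. Spatial
structure enters through queen contiguity: tracts sharing any border point,
corners included, are neighbours.

The package works on any data supplied in this schema; it also ships a
synthetic generator (`simulate_tracts()`) so that every stage can be
exercised — and, more importantly, *calibrated* — against known ground
truth.

## Transportation-noise Monte Carlo aggregation

Raw transportation-noise data arrive as point estimates of 24-hr A-weighted
levels (dBA) within each tract. `aggregate_noise()` converts them to a
percent-of-residents-exposed indicator: in each of `n_reps = 100`
replicates it draws, with replacement, one level per resident and computes
the percent strictly above the 70 dBA hazard threshold; the tract indicator
is the mean over replicates. Two conventions are fixed deliberately:

* the threshold is strict (`> 70`), so a point estimate of exactly 70 dBA
  is not hazardous;
* each tract's random stream is derived from `(seed, tract_id)`
  (`derive_seed()`), making per-tract results independent of processing
  order and stable under parallel or partial re-runs.

Resampling is plain iid within and across replicates. The estimator is
unbiased for the point-set exceedance fraction; with population $N$ its
per-replicate standard error is the binomial
$\sqrt{p(1-p)/N} \times 100$, the scale used by the calibration tests.
A zero-population tract yields 0% with a warning rather than an error,
matching the read-time philosophy of flagging rather than dropping.

## Spatial inequity models: Leroux CAR regression

Occupational inequity across the minority gradient is modelled per
indicator with a Bayesian conditional autoregressive (CAR) Poisson
regression:

$$y_i \sim \mathrm{Poisson}\!\left(\exp(\mathbf{x}_i^\top\beta +
\log o_i + \phi_i)\right), \qquad
\phi \sim \mathcal{N}\!\left(\mathbf{0},\; \tau^2 Q(\rho)^{-1}\right),$$

with Leroux-form precision $Q(\rho) = \rho (D - W) + (1-\rho) I$, where
$W$ is the queen-contiguity matrix and $D$ its degree diagonal. The
dependence parameter $\rho$ interpolates between independent random
effects ($\rho = 0$) and the intrinsic CAR ($\rho \to 1$), and is sampled
with a uniform prior; this nests both limiting behaviours without
committing to either. The five day-count indicators are modelled as plain
counts; noise is the count of noise-exposed workers with a
$\log(\text{workers})$ offset, so its coefficients are prevalence ratios.
Minority composition enters as ten left-closed deciles
$[0,10), \dots, [80,90), [90,100]$ with the first as reference
(`minority_decile_design()`); every model adjusts for population density,
percent under 5 and percent over 64 (standardized internally).

Estimation is Metropolis-within-Gibbs (`fit_car()`, inner loops in C++):
a block random-walk for $\beta$ whose proposal covariance comes from the
maximum-likelihood GLM fit, scaled by $2.38^2/p$ and adapted during
burn-in; univariate Metropolis updates for each $\phi_i$ (conjugate
normal draws in the Gaussian family); conjugate inverse-gamma updates for
$\tau^2$ (and the Gaussian noise variance); and a random-walk update for
$\rho$ whose log-determinant term uses the precomputed eigenvalues of
$D - W$. Priors are weakly informative: $\beta \sim N(0, 10^2)$ on the
log scale (effectively flat — scaled to the outcome — for Gaussian fits)
and $\mathrm{IG}(1, 0.01)$ for variances. At least two chains run by
default; split-chain $\widehat{R}$ and effective sample sizes (Geyer
initial-positive-sequence estimator) are reported per coefficient.
Posterior summaries are equal-tailed 95% credible intervals; exponentiated
(rate-ratio) summaries are the exponential of the linear-scale quantiles,
which is exact because the transform is monotone.

Tracts left without neighbours (possible after subsetting to the
HOLC-graded tracts) receive independent zero-mean effects — the $d_i = 0$
limit of the Leroux conditional — with a warning.

Design notes:

* `spatial = FALSE` collapses the sampler to a Bayesian GLM; its posterior
  means must match the ML fit within 0.02 on the log scale, the package's
  oracle-equivalence check.
* The redlining battery (`redlining_exposure_models()`) fits one model per
  indicator on the HOLC subset with a grade-D-vs-(A–C) indicator: Poisson
  (rate ratios) for count-like occupational outcomes, Gaussian (mean
  differences) for continuous environmental ones. The spatial random
  effect itself is the only random term — no additional city intercept is
  introduced, since no grouping variable is part of the schema; this is a
  documented reading, not an omission.
* Default desk-scale MCMC in the pipeline is 2 chains, 1,000 burn-in,
  2,000 kept draws; `fit_car()`'s own defaults are longer (5,000 / 10,000
  thinned by 5). Both are configurable; the acceptance checks use
  problem sizes of a 20×20 lattice with 1,000 / 2,500 per chain, where
  slope recovery is well calibrated.

## Exposure-profile clustering

`cluster_exposures()` z-normalizes the 13 indicators (mean 0, variance 1;
Euclidean distance is then implied) and runs k-means with 25 restarts for
each candidate $k$ in 2–10, selecting the $k$ that maximizes the average
silhouette width; ties break toward the smaller $k$. No dimension
reduction precedes clustering: collinearity among overlapping exposures is
a feature of cumulative-burden analysis, not a nuisance. Clusters are
relabelled by increasing mean normalized exposure so the top label is
always the cumulatively high-exposure cluster, and per-cluster profiles
are reported in raw units.

A practical caveat the synthetic experiments make visible: when two
archetypes differ mainly on a minority of the 13 axes (e.g. two clusters
with similar occupational but different environmental burdens), the
average silhouette can prefer merging them. Selection is reliable when
centroids separate across most axes relative to within-cluster spread; the
package's selection test therefore uses well-separated profiles, and on
borderline data the `silhouette_by_k` vector should be inspected rather
than trusting the argmax blindly.

Descriptive companions: `describe_exposures()` (median, IQR, range,
13×13 Pearson correlations, with constant indicators reported as missing)
and `inequality_curve()`, a Lorenz-style construction — tracts sorted
ascending by percent minority, cumulative population share against
cumulative population-weighted exposure share — whose area deviation from
the diagonal (trapezoid rule) is 0 for constant exposure and positive when
exposure concentrates in high-minority tracts. The curve convention is
fixed here because the quantity itself does not have a single standard
construction.

## Joint mixture effects: quantile-counterfactual boosted trees

`fit_qgcomp()` estimates the joint effect of a set of focal exposures on a
binary outcome, g-computation style, with gradient boosted classification
trees (xgboost; 500 trees, learning rate 0.05, depth 3, subsample 0.8 by
default — only the tree count is study-prescribed, the rest are
conventional and configurable). For each grid quantile $q$ the focal
columns are set to their empirical $q$-quantiles (type-7 inclusive linear
interpolation — quantile dialects differ, so this is pinned) while
covariates keep observed values; predicted probabilities are averaged
*before* conversion to odds, giving a marginal estimand, and expressed as
an odds ratio against the median reference, at which the OR is exactly 1
by construction. Percentile 95% bounds come from bootstrapping tracts with
replacement and repeating the entire procedure, quantile computation
included; per-replicate seeds derive from the master seed. Bounds are
widened, if necessary, to bracket the point estimate. Partial-dependence
curves sweep one focal variable at a time over its observed quantiles,
with the same odds-ratio convention against the variable's median.

Because the counterfactual sets every focal column to a single point, the
estimate at extreme quantiles rests on the fitted surface at a sparse
corner of exposure space; single-dataset estimates are therefore noisy
even at a few thousand tracts, and the calibration tests aggregate over
simulated datasets (medians, interval coverage) rather than asserting
single-fit accuracy.

Two preconfigured analyses mirror the study design:
`marginalization_analysis()` (odds of top-cluster membership as percent
minority, percent low-income and percent without high-school diploma move
jointly across quantiles 0.1–0.9, adjusted for density, age structure,
county one-hot and centroid) and `redlining_analysis()` (odds of grade D
on the HOLC subset as all 13 exposures move jointly across 0.15–0.9,
adjusted for the two socioeconomic percentages; 1,000 bootstrap replicates
at study scale, configurable down). The two grids differ per analysis by
design.

## Composite EJ scoring

`compute_scores()` rebuilds a CalEnviroScreen-style composite: each
indicator is percentile-ranked across tracts (ties share the mean rank;
the percentile of rank $r$ among $n$ is $100\,r/n$ — fixed for bit-exact
golden tests); category scores average member percentiles; each subscore
is the weighted mean of its category scores; subscores are scaled 0–10 by
dividing by the maximum across tracts; and the overall score is the
product of the conditions and population subscores, 0–100. The subscore
scaling is not printed in the source tool's public description; the
CalEnviroScreen convention is adopted as a documented compatibility
assumption, and by default the product is reported directly on 0–100
without a final re-ranking. Screening tools differ in that last step:
`overall_scale = "percentile"` percentile-ranks the product, so a 90
threshold flags the top decile by construction. The two conventions give
identical orderings; on synthetic data the product scale rarely exceeds
90 unless the two subscores are strongly correlated, which is worth
keeping in mind when interpreting hotspot counts. Scores at or above 90
flag the most burdened (hotspot) tracts.

Three shipped schemes (`ej_scheme()`):

* `miejscreen_base` — conditions = environmental exposures (weight 1) +
  environmental effects (weight 0.5); population = sensitive populations +
  socioeconomic factors.
* `occupational_conditions` — adds the six occupational indicators to the
  conditions subscore at weight 1.5, making the occupational block equal
  in weight to the environmental block (1 + 0.5).
* `occupational_population` — the sensitivity variant: occupational
  indicators join the population subscore, equally weighted with sensitive
  populations and socioeconomic factors.

`compare_schemes()` crosses the hotspot rule under two schemes into four
classes (both, base-only, augmented-only, neither); the augmented-only
class — tracts identified as most burdened *only* when occupational
exposures are considered — is the quantity of policy interest, reported
with its resident total.

Percentile ranking makes all scores invariant to strictly monotone
transforms of any raw indicator.

## The synthetic generator and what passing tests mean

`simulate_tracts()` emulates the joint structure the analyses assume,
with every generating parameter surfaced in `truth`:

* demographics from scaled Beta marginals chosen so medians sit near
  realistic statewide values (median percent minority ≈ 15, low-income ≈
  31, no-HS ≈ 6); percent minority is spatially smoothed through a
  Gaussian copula over a lattice GMRF unless `demog_spatial = FALSE`;
* occupational day counts are Poisson with log-rate = log(cluster
  baseline) + `demog_effect` · minority/100 + a proper Leroux GMRF drawn
  with the same precision the CAR sampler assumes — parameter-recovery
  tests simulate from the fitted model's own family;
* noise-exposed workers are Binomial with a logit-linear prevalence;
* environmental indicators are lognormal about 3 cluster centroids
  (mixing weights 0.31/0.41/0.28) patterned on the low-occupational /
  high-occupational / cumulatively-high archetypes, with coefficient of
  variation 0.12;
* a configurable fraction of tracts (default 26%, skewed toward dense
  tracts) carries HOLC grades, with grade D assigned by a logistic model
  in centred exposure percentile ranks;
* per-tract noise point sets are mixtures around the cluster's
  transportation-noise target on 45–95 dBA.

For recovery tests the default `demog_spatial = TRUE` matters: a spatially
smooth covariate is partially confounded with the spatial random effect
(the field absorbs part of the slope), which attenuates estimates — a real
phenomenon in areal regression, not an implementation artifact. The
recovery and coverage tests therefore switch to spatially independent
demographics, which isolates the property being tested (interval
calibration under the model); the confounded setting remains available and
is the realistic default elsewhere.

What the generator does *not* reproduce: any real state's joint exposure
distribution, geographic realism beyond a lattice, environmental-effects
indicators (placeholder `eff_*` columns stand in for the scoring stage),
or the magnitude of real spatial confounding. Passing tests demonstrate
the estimators are correctly implemented and calibrated under the stated
models — not that real data meet those models.

## Pipeline, determinism, and problem sizes

`run_pipeline()` sequences the stages (noise aggregation → descriptives
and inequality curves → CAR inequity battery → clustering →
marginalization → redlining CAR + boosted-tree analyses → scoring and
scheme comparison) after applying the analysis filter: tracts with fewer
than 20 working residents, or zero population, are excluded — at analysis
time, not read time, so I/O stays pure. Stage failures are recorded and
independent stages still run. Every stochastic stage derives its seed by
stable-hashing the stage name with the master seed, so toggling one stage
does not shift another's stream, and a rerun with the same configuration
reproduces identical outputs — verified by comparing report hashes. The
run report records counts at each filter, seeds, a configuration hash, and
a hash over all deterministic stage outputs.

Problem sizes used by the shipped checks were chosen for desk-scale runs:
20×20 lattices for CAR calibration (100 simulated datasets), 12×12 draws
for cluster selection (50 draws), n = 2,500 with 50 bootstrap replicates
for the boosted-tree calibration, and a 30×30 lattice for the end-to-end
determinism check. All scale up by configuration.

## Known limitations

* The dense eigendecomposition of $D - W$ (for the $\rho$ update) and the
  GMRF Cholesky in the generator are $O(n^3)$; practical up to a few
  thousand tracts, beyond which sparse methods would be needed.
* Quantile-counterfactual estimates at extreme quantiles are inherently
  high-variance (corner extrapolation); intervals are honest about this,
  point estimates from a single dataset should not be over-read.
* The "mixed-effects" redlining contrast contains no city-level intercept
  (no such variable exists in the schema); whether intervals should be
  read as frequentist confidence or Bayesian credible intervals is a
  modelling stance — here they are equal-tailed posterior intervals.
* Composite-score conclusions are sensitive to category weights; the
  shipped schemes make the weighting explicit and alternatives are one
  `score_scheme()` call away.
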