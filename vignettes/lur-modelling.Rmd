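---
title: "Land use regression modelling of PM2.5 with lurkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression modelling of PM2.5 with lurkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Land use regression (LUR) estimates a pollutant surface by regressing
monitor concentrations on GIS-derived predictors and evaluating the
fitted equation at every grid cell:

$$ Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \dots + \beta_n X_n + \varepsilon $$

where $Y$ is the monthly mean PM2.5 concentration at a monitor
(µg/m³) and the $X_i$ are candidate predictors: summed land-use class
areas and mean greenness (NDVI) within circular buffers around the
monitor, distances to the nearest point/line feature (airports, major
roads), monthly meteorology interpolated from a sparse station network,
season indicators, and optionally co-pollutant concentrations. The
model assumes a linear, additive, spatially and temporally stationary
relationship with homoscedastic errors — strong assumptions that the
supervised selection partially compensates for by only admitting terms
whose sign matches prior knowledge.

`lurkit` implements the full pipeline on a planar 50 m grid: predictor
construction (`focal_stat`, `nearest_distance`, `idw`), design assembly
(`assemble_design`), model development (`supervised_stepwise`),
validation (`kfold_cv`) and mapping (`predict_surface`,
`exceedance_summary`), plus a seeded synthetic-scene generator
(`simulate_lur_study`) that provides a known ground truth so every
stage can be tested quantitatively.

## Buffer predictors

Buffer predictors are circular-kernel focal statistics. A cell belongs
to the kernel when its center lies within the radius of the focal
cell's center (`circular_kernel`), the circle semantics of standard GIS
focal-statistics tools; the tool convention had to be made explicit
here because different GIS packages disagree on edge membership. Land
use enters as the summed class area in hectares within the buffer —
the magnitude that makes a residential-area coefficient of a few
hundredths per hectare meaningful — and NDVI as the buffer mean;
`fraction` or m² views are a rescaling away. Edge cells use in-grid
kernel members only (no padding), and an all-missing neighborhood
propagates `NA`.

The default radius ladder spans 250–5000 m and includes the
intermediate radii (1250, 1750, 4250, 4750 m) that buffer-selection
studies commonly report. Adjacent radii of one layer are strongly
correlated by construction; no same-layer exclusion rule is imposed —
the VIF gate alone arbitrates, so a model may legitimately retain two
radii of one layer when collinearity permits.

Focal kernels are evaluated in compiled code, accumulating in IEEE
double precision in a fixed kernel-offset order. This makes results
reproducible bit-for-bit by any enumeration that visits offsets in the
same order, which the test suite exploits to demand *exact* (not
approximate) agreement with a brute-force oracle.

## Meteorology interpolation

Station meteorology is interpolated by inverse distance weighting with
$w_i = d_i^{-p}$, $p = 2$ by default (the conventional choice; the
exponent is exposed in `idw_config`). All stations are used — LUR
study areas typically have too few stations for a neighbor cutoff to
help — and a 1 m snap tolerance returns a station's own value at
coincident queries, avoiding the $d = 0$ singularity. IDW output is a
convex combination of station values, hence exact at stations and
bounded by their range. Daily series are aggregated to months first
and interpolated second; with complete synthetic series the order only
matters through missing data, and aggregate-first is the cheaper
route. A month is emitted when at least 75% of its days are observed
(`min_completeness`), a conventional completeness rule chosen because
the monthly-aggregation step needs *some* rule and the data sources
this pipeline emulates do not state one.

## Supervised stepwise selection

Model development mirrors the supervised forward-backward procedure of
buffer-based LUR studies:

1. **Screen.** Spearman rank correlation of each candidate with the
   response; candidates whose correlation sign contradicts their
   a-priori direction (e.g. positive greenness) are dropped, as are
   zero-variance columns. Only the sign is screened; no magnitude
   threshold is applied.
2. **Rank.** Remaining candidates are ordered by single-predictor
   $R^2$; after each accepted term, remaining candidates are re-ranked
   by the $R^2$ of the model *with* that candidate added (conditional
   gain), reflecting that the search continues from the current model
   rather than from the original univariate ordering.
3. **Gate.** A candidate is added only if, in the tentative fit, its
   coefficient p-value is below `p_enter` (default 0.1), every VIF is
   below `vif_max` (default 3), and no coefficient with a nonzero
   direction prior flips sign. After each addition, terms whose
   p-value has risen above the threshold are removed, highest first.
4. **Stop.** Selection ends when no remaining candidate is addable;
   the final model is re-fit and all gates re-verified.

Two thresholds called "significance" coexist in this literature: the
coefficient p-value gate (0.1) and the Spearman correlation of the
pre-screen. They are distinct quantities here, named `p_value` and
`spearman_rho`, to avoid the symbol collision.

Ties in any ranking are broken lexicographically by variable name, so
the procedure is fully deterministic: the same design and configuration
reproduce the same `SelectionTrace` (an ordered log of every add,
remove and skip with its reason), and replaying the trace reproduces
the model.

Partial $R^2$ is the squared partial correlation of a term with the
response given the other terms, computed as $t^2/(t^2 + \nu)$ from the
term's t-statistic with $\nu$ residual degrees of freedom, and verified
against a residual-on-residual (Frisch–Waugh) oracle. Reported partial
$R^2$ values in the applied literature are not always mutually
consistent, so this package fixes one definition and tests it.

OLS fits use a QR decomposition with two-sided t-tests; RMSE is the
root *mean* squared residual ($\sqrt{\mathrm{SSE}/n}$). Rank-deficient
designs raise an error naming the aliased columns rather than silently
dropping them.

## Cross-validation and mapping

`kfold_cv` partitions station-month observations into $k = 10$ seeded
folds of near-equal size (so each training split holds $(k-1)/k$ of
the rows within one observation), refits the selected terms on each
training split and predicts the held-out fold. The headline metrics
are pooled over concatenated out-of-fold predictions; per-fold values
are also reported. The fold unit is the individual observation: with
very few monitors (two, in the sparsest network this emulates)
stratifying by station is impossible, though a full re-selection mode
(`refit_selection = TRUE`) is provided for honesty analyses of the
selection itself.

`predict_surface` evaluates the fitted equation cellwise from one
raster per term (static layers broadcast across months). Negative
cells can be floored at zero in exported maps — never in CV metrics —
with the floored count logged. `period_average` gives yearly and
pooled maps, and `exceedance_summary` counts cells above named
guideline thresholds (defaults: WHO annual 10 and 24-h 25 µg/m³,
Indonesian national annual 15 and 24-h 65 µg/m³).

## The synthetic scene generator

The generator emulates the statistical structure the analysis assumes,
not any real geography:

- **Land use** — a smooth Gaussian random field classified by its
  empirical quantiles, so each class hits its target area fraction
  almost exactly while staying spatially contiguous; plus simple
  vector features (road/railway chords, airport and quarry points).
- **NDVI** — a static smooth field plus a seasonal cycle, a yearly
  anomaly and small per-layer smooth perturbations, produced at the
  16-day cadence of satellite vegetation composites and composited
  monthly by cellwise maximum (the max-value-composite convention;
  mean compositing is available). Values are clamped to $[-1, 1]$ and
  kept on the native 0–1 index scale — sources that store NDVI as
  integers scaled by $10^4$ are handled by a reader-side scale factor
  rather than by guessing inside the generator.
- **Meteorology** — per variable: a linear spatial gradient with random
  orientation, a station-level micro-siting offset, a sinusoidal
  seasonal cycle, monthly and yearly anomalies, and iid daily noise,
  with physical bounds enforced (humidity in [0, 100]%, non-negative
  wind speed/rainfall/UV).
- **PM2.5** — drawn from a known linear ground truth over the
  assembled candidates, truncated at zero; the exact noiseless
  predictor and the untruncated draws are returned so tests never have
  to reason about the truncation.

Two generator design points deserve emphasis. First, all seasonal
variables share the annual frequency, and monthly averaging removes
most daily noise; with rigid sinusoids alone, any three seasonal
variables become numerically collinear (two fixed-frequency phases span
the space) and even the *true* model fails a VIF < 3 gate — which
contradicts the VIF magnitudes (≈1.2–1.8) that published
temperature-plus-humidity models report. Distinct seasonal phases
(humidity peaking near day 20, greenness near 140, temperature near
260, rainfall near 90) together with the monthly/yearly anomalies and
micro-siting offsets keep cross-variable correlations realistic and the
truth identifiable. Second, the default ground truth (temperature
+5.8, relative humidity −0.78, NDVI within 1500 m −77, residential area
within 1000 m +0.05 per hectare, intercept −75) mirrors the structure
and magnitudes of a tropical-megacity PM2.5 model, and its residual
noise is calibrated so the true-model population $R^2$ is 0.8
(`noise_for_r2`), the regime in which recovery experiments are
informative.

What the generator does **not** emulate: real land-use geography and
class adjacency patterns, cloud/QA artefacts in satellite indices,
missing-data patterns in station series, wind-direction effects, or
spatially correlated model errors. Passing tests therefore show the
*procedure* is correct and well-calibrated under its own assumptions —
not that any particular real-world deployment will reach a given
$R^2$.

## Problem sizes and numerical choices

The showcase analysis (`analysis/01–05`) uses the default scene:
200×200 cells of 50 m (10×10 km), 17 monitors, 5 meteorology stations,
36 months, 40 candidate predictors. Multi-seed selection experiments
(the gate-invariant, recovery and null-control checks, and the
acceptance script) use a 100×100-cell scene with 30 months trimmed to
exactly n = 500 station-month rows — the same candidate set at a size
where 50 seeded replicates run comfortably on one core.

Other fixed choices: coordinates are planar meters, x right / y up,
half-open cell intervals (a point on a shared edge belongs to the
east/north cell); kernels always include the focal cell; perfect
collinearity reports an infinite VIF and fails the gate; the stepwise
loop carries a visited-state cycle guard and a step cap (100) so
alternating add/remove sequences cannot loop; zero-variance response
or predictors are rejected with explicit reasons.

## Limitations

- Greedy selection with gates is not best-subset search; the suite
  checks agreement only on engineered instances where the greedy path
  is unambiguous.
- Observation-level CV is optimistic about spatial transfer: folds
  share stations. Leave-station-out behaviour can be approximated with
  `refit_selection` on station-blocked subsets but is not a packaged
  mode.
- The generator's truncation-at-zero is applied to the response only;
  with the default calibration truncation affects a negligible share
  of draws, but extreme user configurations (mean near zero) would
  bias low concentrations.
- No CRS handling: all inputs are assumed to share one planar metric
  system. Reprojection is a documented pre-step outside the package.
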