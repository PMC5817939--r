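---
title: "Thermal-stress indices and statistically optimized coral-bleaching prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-stress indices and statistically optimized coral-bleaching prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbleach)
```

## The problem

Mass coral bleaching is driven primarily by accumulated heat stress: sea-surface
temperatures (SST) persisting above the local climatological summer maximum expel
the corals' symbiotic algae.  The operational warning system for this is the
degree heating week (DHW): positive-only SST anomalies ("HotSpots") above the
maximum monthly mean climatology (MMM), accumulated over a trailing 84-day
window after discarding days whose anomaly falls below a *filtering threshold*,
conventionally 1 °C.  A DHW above 4 °C-weeks is the conventional bleaching
alert.

`reefbleach` implements this index family and everything needed to *optimize*
it against point observations of bleaching: the climatological baselines, the
ancillary environmental covariates (UV-B, turbidity, current speed, depth,
cooling), binomial-logit and random-forest occurrence models, and the
cross-validated threshold and variable searches scored by the true skill
statistic.  Because satellite SST archives and field observations are bulky and
access-restricted, the package also ships a synthetic-data generator with known
ground truth; every claim the test suite makes is checked against that ground
truth or against independent brute-force oracles.

## Climatological baselines

From a daily SST cube the package builds, per cell:

* **MMM** — the maximum of the 12 climatological monthly means.  Before taking
  the maximum, each monthly mean is *recentered* to the temporal midpoint of
  the heritage coarse-resolution baseline era by subtracting
  `slope × (full_span_center − heritage_center)`, where `slope` is the per-cell
  least-squares linear trend of the monthly mean series.  The default centers
  follow the month-midpoint convention: the mean month-midpoint of 1985–2015 is
  2000.5 and of 1985–1990 ∪ 1993 is 1988.786 (`recenter_spec()`).  The trend is
  fitted on the full monthly series against the mean decimal year of each
  month's days, which makes the fit exact for a linearly trending cube.
* **MMM_max** — the mean over years of each year's warmest monthly mean.
  Because the warmest calendar month may shift between years, MMM_max ≥ MMM
  always; the package asserts this on every synthetic world.
* **σ_m** — the sample standard deviation (n − 1) of the annual maximum
  monthly SST, used both as a model covariate (`v`) and to scale thresholds.
  The definition is the standard sample SD; for a 31-year record with true
  interannual SD 0.5 °C the sampling distribution puts ~95 % of estimates in
  [0.35, 0.65], which the acceptance suite verifies by simulation.

Product harmonization (`harmonize_products()`) adds the per-calendar-month
overlap-period climatology difference of a fine product to a coarse one;
spatial downscaling and coastal gap-filling use bilinear and inverse-distance
(power 2, 12 neighbors, great-circle distances) interpolation.

## The index family

All indices are trailing windows ending on the observation date (the
observation day is the last day of the window):

| index | window | definition |
|---|---|---|
| DHW  | 84 days  | (1/7) Σ HS, over days with HS ≥ threshold (°C-weeks) |
| DHM  | 12 months| Σ monthly HS, months with HS ≥ threshold (°C-months) |
| DCW  | 84 days  | (1/7) Σ (MMM − SST) over non-negative cool-spots (°C-weeks) |
| weekly / monthly SST | 7 / 30 days | trailing arithmetic mean (°C) |

Two conventions matter and are fixed throughout: the filter comparison is
**≥** (a HotSpot exactly at the threshold is accumulated, *in full* — the index
sums HS, not HS − threshold), and alert comparisons are **strict >** (DHW of
exactly 4 is not an alert).  The filtering threshold is either a constant α
(searched over [0, 1.5] °C) or β·σ_m per cell (β over [0.1, 2.5]); DCW has no
filter (cutoff fixed at 0).  Standard alerts: monthly SST > 30 °C, weekly
SST > 31.5 °C, DHW > 4, DHM > 1, and the σ_m-scaled rule DHW > 2.45·σ_m —
2.45 °C⁻¹ being the global reciprocal median of σ_m; the rule is applied as a
plain numeric comparison even though the two sides carry different units.

Missing days inside a window are tolerated up to 10 %, with the accumulated sum
renormalized by `84 / valid days`; beyond that the window is rejected.
Satellite gaps are routine and this keeps the index unbiased for short gaps
without hiding long ones.

## Models and evaluation

The binary bleached/nonbleached response is modeled two ways, deliberately
without interactions or polynomial terms:

* **GLM** — binomial errors, logit link (`stats::glm`).  The binomial
  assumption is checked as residual deviance per residual degree of freedom
  < 1.5, and perfect separation is flagged as non-convergence.
* **RF** — a *regression* forest on the 0/1 response
  (`randomForest`, 500 trees, `mtry = ⌊p/3⌋`, seeded), so predictions are
  ensemble means in [0, 1].

Skill is scored by confusion-matrix rates at a probability threshold: ACC,
TPR (sensitivity), TNR (specificity) and TSS = TPR + TNR − 1, which is
prevalence-insensitive — important here because nonbleaching records outnumber
bleaching ones.  The *evaluation threshold* is chosen by TPR + TNR
maximization over the unique predicted probabilities, ties broken toward the
smallest candidate (which maximizes TPR).  The implementation is a vectorized
suffix-sum scan; the test suite holds it to exact agreement with an exhaustive
brute-force search on hundreds of random sets.

Cross-validation is repeated random 70/30 splitting (10 repeats by default;
test sets of `round(0.3 n)` rows), with summaries reported as mean ± SE over
repeats.  The evaluation threshold is optimized **on the training
predictions** and applied unchanged to the test set; this avoids leaking test
labels into the threshold.  Because legacy tooling in this field sometimes
optimizes on the test predictions, `threshold_on = "test"` is available as a
compatibility switch.  Splits leaving either class empty are re-drawn.

## The searches

`filtering_threshold_search()` scans the α grid (151 candidates at 0.01
precision) or β grid (241 candidates), *recomputing the index from cached
per-record HotSpot windows* for every candidate and re-running the repeated
cross-validation with identical splits (common random numbers), so candidates
differ only through the index.  Grid values are generated by integer steps
(`i/100`) to keep the cardinalities exact.  `variable_combination_search()`
evaluates the 15 non-empty subsets of the four optional covariates
(σ_m `v`, turbidity `k`, depth `d`, current speed `s`), each on top of the
thermal index plus the two always-included covariates (cooling `c` and UV-B
`u`); the empty subset is computed too but reported separately for
transparency.  Run jointly, the factorial is
`repeats × 15 × {151 | 241}` = 22,650 or 36,150 fitted models, which the
acceptance suite verifies against the literal row count of the search trace.

A property worth knowing: selection by outright maximum mean test TSS reliably
*finds* informative covariates but does not reliably *exclude* uninformative
ones, because an extra null covariate moves test TSS only within its sampling
noise.  The package therefore also offers `parsimony = "one_se"`, which picks
the smallest combination within one standard error of the maximum; even under
that rule, exact support recovery on synthetic worlds plateaus around 70–90 %.
Interpreting a selected combination as "the minimal true driver set" is
unsupported under either rule; interpreting it as "a maximally skillful set"
is.

## Spatial prediction and the UV-screening scenario

`predict_grid()` averages the probabilities of the 10 cross-validation models
cell-wise; the binary alert layer thresholds the ensemble mean at the mean of
the per-repeat optimized thresholds (per-member binarization then voting is
available by flag).  The prediction month is each cell's own warmest month of
the year (`warmest_month()`), since a fixed calendar month misrepresents cells
whose seasonal peak shifts.  `bleaching_frequency()` converts yearly binary
maps into `100 × alert-years / years`.  The management scenario
(`scenario_spec()`) multiplies UV-B by 0.6 and turbidity K490 by 1.4 — the
effect of screening sunlight with fishnets — and is guaranteed never to raise
predicted probability under any fitted model with a positive UV-B and negative
turbidity coefficient.

## The synthetic world

`synthetic_scenario()` defines the generating process; its defaults are the
package's statement of realistic study conditions and are not adjusted
elsewhere:

* daily SST = subtropical seasonal cycle (mean 25 °C, amplitude 4 °C, peak at
  day 227) + latitudinal gradient (−0.15 °C/°lat) + linear warming
  (0.02 °C/yr) + per-cell-and-year interannual offsets (SD 0.57 °C, matching
  the median summer-maximum variability of subtropical reef regions) +
  optional Gaussian-footprint heat waves + daily noise (0.3 °C);
* smooth positive covariate fields whose grid mean equals the requested mean
  exactly (UV-B with a July-peaking seasonal cycle, K490, current components,
  depth);
* 668 observations (a realistic citizen-science campaign size) drawn in the
  July–October bleaching season, with bleached flags Bernoulli from a known
  logistic model whose default coefficients follow the usual signs and
  magnitudes (positive DHW and UV-B, negative cooling, turbidity and depth);
* straight-line 6-hourly typhoon tracks with a mid-track wind maximum.

A single master seed feeds independent per-generator substreams, so adding one
generator never perturbs another and a fixed seed gives bit-identical worlds.
What the generator does *not* emulate: ocean dynamics, advection, cloud-driven
gaps, observer bias, spatial clustering of observations, or any real coastline
— so green tests demonstrate correctness of the statistical machinery under
known conditions, not field-data performance.  Quantities that depend on the
original deposited field dataset (its record counts and its cross-validated
TSS) can only be recomputed with that table present;
`reproduce_field_study()` is the entry point and the corresponding acceptance
test states this requirement explicitly.

`simulate_stress_windows()` is a purpose-built benchmark for the
filtering-threshold search: sub-threshold "haze" days carry no information
while days just above the planted threshold carry all of it, so candidates
below the truth admit noise and candidates above it discard signal.  Under
those conditions the search recovers a planted 0.5 °C threshold to within
0.05 °C on average across replicate worlds.

## Numerical choices and degenerate inputs

* Grid cardinalities come from integer stepping, never floating-point `seq`.
* Threshold ties break toward the smaller candidate (maximizes TPR); search
  ties break toward the smaller threshold.
* Constant residuals make Moran's I undefined and are reported as such (NA),
  never as zero; significance uses 999 seeded permutations with inverse
  great-circle-distance, row-standardized weights (cutoff configurable) —
  scheme logged because the field rarely states one.
* Monthly aggregation requires ≥ 50 % day coverage per cell-month.
* Collinearity screening (|r| > 0.7, Pearson) drops the lower-priority member
  (thermal index > UV-B > others, configurable); constant columns are flagged
  rather than correlated.
* QC reclassification (non-thermal bleaching with DHW = 0 set to nonbleached)
  is idempotent and can only flip bleached → nonbleached.
* The record parser rejects rows (not files) for range violations, unparseable
  dates, or a `none` severity with a positive bleached flag, reporting line
  numbers.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on synthetic worlds
sized for a laptop: climatology checks on a 10 × 10 × 31-year cube; oracle
equivalence on 1,000 random 84-day series; threshold-search recovery on 10
replicate worlds of 800 records at 0.05 grid precision; the full
22,650/36,150-model factorials on a 24-row table with a constant-probability
stub model (the factorial structure, not the fit, is what those counts
check); and an end-to-end pipeline on a 6 × 6 grid with 668 records.  These
sizes are the package's own choice of a convincing-but-small demonstration;
all of them scale up by configuration.

## Known limitations

* No ordinal severity modeling — the response is binary, as in standard alert
  practice.
* No geocoding, duplicate-observer detection, or basemap rendering.
* Grid I/O is plain-text CSV with a metadata header rather than NetCDF;
  the format round-trips exactly and keeps the package dependency-light.
* The σ_m-scaled alert mixes units by construction (documented above).
* TSS-maximizing variable selection is not support-consistent (documented
  above).
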