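---
title: "Spatializing grazing census data: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatializing grazing census data: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasygraze)
```

## The problem

County livestock censuses report one standard-sheep-unit (SU) total per
county per year. Pixel-level grazing pressure is what ecological analysis
needs, and the mapping from one to the other is underdetermined: infinitely
many pixel fields share the same county totals. dasygraze resolves the
indeterminacy the way dasymetric mapping always does — with an ancillary
weight layer — and then sharpens the result with a machine-learning model
trained across scales, under one hard constraint: the delivered grid must
agree with the census exactly at the county level.

## Pipeline and assumptions

### Sheep-unit conversion

Head counts of eight species are converted by fixed coefficients
(`sheep_unit_coefficients()`; goat 0.8, cattle/yak 5, horse/mule 6, donkey
3, camel 7). The conversion is linear, so it commutes with any spatial or
temporal aggregation. Missing county-years are filled by scaling the
nearest recorded county value with the parent (city/province) series'
relative trend; with no parent series the fallback is linear interpolation
between recorded years, constant beyond them. National yearbooks rarely
publish their own infilling rule, so ours is deliberately simple, flagged
in a `provenance` column, and easy to substitute.

### Suitable grazing area

Grazing is restricted to grassland, below an altitude ceiling, away from
towns, and outside nature-reserve core zones. The altitude and
town-distance cutoffs are **required configuration**, not constants baked
into the code (example defaults 5500 m and 2 km): they encode management
judgments that differ between regions, and every run logs the values used
together with per-rule removal counts. The final mask is order-invariant;
only the attribution of removals to rules depends on rule order.

### Disturbance index and dasymetric distribution

Grazing depresses vegetation below its undisturbed potential, so the
deviation trajectory `D_i = NDVI_obs − NDVI_pot` (length T) carries the
grazing signal. Scoring each pixel by the Mahalanobis distance of `D_i`
from the mean deviation `u` accounts for correlated, unequally scaled time
steps:

$$AD_i = \sqrt{(D_i - u)^\top \Sigma^{-1} (D_i - u)}.$$

Two statistical choices are open and we fix them as follows:

* `u` and `Σ` are computed over **all** valid masked pixels, not per
  county, so the disturbance scale is common across counties and county
  weights are comparable;
* the dasymetric weight is the **raw** AD value (no rank or power
  transform) — the simplest reading; alternatives can be applied to the AD
  matrix before `dasymetric_distribute()`.

Pixels with any missing NDVI step are excluded from both the statistics and
the distribution. Conservation is structural: zonal sums of the distributed
field equal census totals to floating-point accuracy.

The index assumes the NDVI deficit is grazing-driven. Wild herbivory,
drought and fire violate that assumption in real data; the synthetic
generator deliberately builds the assumption in, which is exactly why
passing tests certify the machinery, not the ecological attribution.

### Cross-scale features

Training a regression on 25–250 county means and predicting at thousands of
pixels is a scale mismatch: county means compress the response range, and
pixel extremes fall outside the training support. The cross-scale remedy is
to cluster each county's distributed densities (1-D Ward agglomeration)
into groups, selecting the group count k by minimizing the Davies–Bouldin
index

$$DBI_k = \frac{1}{k}\sum_x \max_{y\ne x}
  \frac{\bar a_x + \bar a_y}{|\delta_x - \delta_y|},$$

with `ā` the mean within-group distance to the centroid and `δ` the
centroid. One training row per group (group means of response and
covariates) widens the response range and multiplies the sample size.
Choices made here:

* clustering operates on the 1-D distributed SU values only (not the
  multivariate covariates): the groups are meant to grade the *response*
  within a county;
* candidate k ranges over 2–6 per county (capped at the pixel count);
  counties too small to cluster contribute their county mean, so the
  group table degrades gracefully to the traditional table;
* DBI ties resolve to the smaller k (parsimony); coincident centroids give
  an infinite score; all-identical values collapse to k = 1, which makes
  the cross-scale table literally identical to the county table when
  within-county heterogeneity vanishes — a property the test suite asserts.

### Partitioned random forests

Low-density and high-density grazing respond to covariates differently, so
samples are split at grassland-type-specific carrying-capacity thresholds
(alpine meadow 0.43, alpine steppe 0.35, alpine desert steppe 0.21 SU/hm²;
`capacity_threshold()` derives alternatives from forage yield, utilization,
intake and grazing days). A row exactly at its threshold goes to the low
partition. One forest is fitted per partition on `log1p(density)` — the
log admits zero-density groups, and the offset is recorded in the model
object. Samples split 3:1 into train/test; held-out R²/RMSE/MAE are stored.
Forests use 500 trees, `ranger` defaults otherwise, one thread and fixed
seeds, so refits are bit-identical. A partition with fewer than 8 samples
triggers a single-model fallback with a warning rather than a failure.

At prediction time the partition of a pixel is unknown (its density is the
thing being predicted), so routing needs a provisional estimate: a pooled
forest fitted on all samples predicts first, the pixel is routed
low/high by comparing that provisional density to its type's threshold, and
the routed forest produces the final value. This is deterministic and
recorded; it does introduce routing error near thresholds, which is
visible in the benchmark as the gap between M2 and an oracle-routed
partition model.

### Residual correction

Forest predictions are biased at the county scale; the correction adds each
county's mean residual `R_j = census_j / n_j − mean(pred_j)` to its pixels.
Where the shift would produce negative densities, values are clipped at
zero and the remaining mass rescaled proportionally over the county
(iterated to a 1e-9 relative tolerance) — preserving nonnegativity *and*
the census total simultaneously. Corrected county means therefore equal
census means exactly, which is why county-level agreement metrics of the
delivered product are near-perfect by construction; honest skill assessment
must use the raw predictions (or, on synthetic data, the pixel truth).

### Validation metrics

R² is the one-minus-error-ratio form `1 − Σ(c−p)²/Σ(c−c̄)²` — identical in
form to the Nash–Sutcliffe efficiency, applied across counties instead of
years — and can be negative for biased predictors; it is *not* a squared
correlation, and the two diverge exactly when bias matters. MRE excludes
zero-census counties (reported separately), mirroring the separate
accounting of counties that cannot be distributed for lack of suitable
pixels.

## The synthetic landscape

`generate_landscape()` builds a fully known test world from a seeded
config:

* **counties**: Voronoi cells of uniformly sampled seed pixels — contiguous,
  irregularly sized, like administrative units;
* **covariates**: Gaussian-smoothed white noise (`spatial_range` sets the
  kernel sd, default 6 px), standardized — spatially autocorrelated without
  the machinery of geostatistical simulation;
* **density truth**: `exp(intercept + 0.8 x₁ + 0.55 x₂ + 0.35 x₃ +
  0.4 x₁x₂)` SU/pixel plus Gaussian noise (sd `noise_sd`, default 2),
  clipped at 0, with a 5%-per-year multiplicative trend. The exponential
  link makes density right-skewed — a lightly grazed majority and a heavy
  hotspot tail — matching both observed grazing-density distributions
  (field values in alpine rangeland span 0–8.5 SU/hm² against thresholds of
  0.21–0.43) and the premise of the model's log-transformed response. The
  published coefficients give variable importance a known ground truth.
  With the default pixel area of 100 hm², the median density of 15 SU/pixel
  is 0.15 SU/hm², and roughly a fifth of pixels exceed their type's
  carrying-capacity threshold;
* **NDVI pair**: potential NDVI is a smooth field in [0.4, 0.95]; observed
  NDVI subtracts a saturating, strictly increasing deficit
  `0.3 d / (30 + d)` of density `d`, plus noise proportional to
  `noise_sd`, clamped so grazing never raises NDVI above potential. With
  zero noise, pixel ranking by NDVI deficit equals ranking by density — the
  idealized form of the disturbance assumption;
* **census**: zonal sums of the truth, so census/truth consistency is exact
  by construction.

What the generator does **not** emulate: real geography and climate
seasonality, wild-herbivore and drought signals in NDVI, census reporting
error, nomadic movement, or any particular region's covariate structure.
Tests passing on these landscapes certify the pipeline's mechanics and its
comparative behavior (cross-scale features help when counties are
heterogeneous), not real-world accuracy.

## Benchmark sizes and determinism

The reference landscape is 60×60 pixels, 25 counties, 8 covariates, 3
years, seed 42 — sizes chosen so the full M1–M4 ladder (4 model fits plus
3600-pixel predictions) completes in seconds while keeping ≥100 group-level
training rows. Everything downstream of a config is a pure function of its
seeds: landscape generation, the 3:1 split, and the forests are all
explicitly seeded, and the test suite asserts end-to-end bit-identical
reruns.

## Known limitations

* Routing error near partition thresholds is intrinsic to hard binary
  routing; soft blending was left out to stay close to the two-model
  design.
* The interpolation rule for missing census years is a documented stand-in;
  provenance flags make substitution safe.
* End-of-year stocking censuses ignore within-year off-take, so absolute
  intensities inherit that bias from the source data.
* County-level residual correction guarantees administrative consistency
  but cannot repair within-county misallocation; pixel-scale skill rests
  entirely on the covariates and the disturbance prior.
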