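---
title: "Mapping forest disturbances in annual Landsat time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest disturbances in annual Landsat time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealdist)
```

## The problem

Insect outbreaks (spruce budworm, hemlock looper, mountain pine beetle and
other defoliators and bark beetles) are a dominant natural disturbance in
boreal coniferous forest, yet unlike wildfire and harvesting they are
rarely present in long-term satellite-derived disturbance records: their
spectral signal is gradual, subtle at low severity, and spatially
heterogeneous within a 30 m pixel. `borealdist` implements a hybrid
two-step method that detects and classifies forest disturbances — insect
defoliation in three severity classes, wildfire, harvesting, windthrow and
water extension — in annual six-band surface-reflectance time series
(blue, green, red, NIR, SWIR1, SWIR2), together with the training-data
construction rules, map assembly and post-processing, and the design-based
validation statistics that go with such a product.

## The two-step model

**Step 1 — detection.** The normalized burn ratio,
NBR = (NIR − SWIR2)/(NIR + SWIR2), is segmented into a continuous
piecewise-linear trajectory per pixel. The fitter despikes single-year
down-up artifacts (undetected clouds), then inserts hinge knots greedily to
a segment budget and backward-prunes knots whose removal is not
statistically significant (F-test, `p_enter = 0.05`). The overfit-then-prune
order matters: a step-like break needs two knots, and forward selection
alone stalls because one hinge at a time is not significant on a step.
Declining vertex runs whose cumulative fitted drop exceeds 0.1 become
candidate disturbance segments; the reported start year is the first year
the cumulative fitted decrease exceeds 0.1, the end year is the run's last
year, and at most the 5 most recent segments per pixel are kept. Only
segments lasting less than 10 years go on to classification.

**Step 2 — classification.** A one-dimensional temporal convolutional
network (TempCNN) classifies a 10-year × 6-band window anchored one year
before each detected break (advanced past missing anchors; clamped to the
last full window of the series, so breaks after `last_year − 9` use the
final decade). The architecture follows the published hyperparameters and
the reference TempCNN block design: three convolution blocks (64 filters,
kernel size 3, same-length padding, batch normalization, ReLU, dropout
0.4), a batch-normalized dense layer of width 64 with dropout, and a
softmax head; trained 50 epochs with batch size 64, weight decay 1e-5 and
a learning rate of 0.001 decreasing every epoch. Batch normalization is
load-bearing, not cosmetic: without it the adjacent defoliation-severity
classes train several recall points worse under identical budgets. Predicted training classes are collapsed to nine map codes
(0 undisturbed, 1 wildfire, 2 harvesting, 3 windthrow, 4 water extension,
5 defoliation-followed-by-harvesting, 6/7/8 low/medium/high severity
defoliation). Rapid codes stamp one year (wildfire segments stretched
beyond 2 years by missing data stamp the segment end); pest codes stamp
every year of the segment.

Defoliation severity is an observable, not a latent state: a drop is `low`
in [0.1, 0.15), `medium` in [0.15, 0.25), `high` at ≥ 0.25, and below 0.1
is excluded. The half-open bins are a package decision — the thresholds are
only published as "greater than / lower than", and half-open intervals
guarantee a partition.

## Design choices that were genuinely open

* **Segmentation internals.** Only the segmentation *contract* (0.1 start
  rule, 5 most recent segments, <10-year classifiability) is published;
  control parameters are not. The fitter exposes `max_segments` (default
  6), despiking (on by default) and the knot-entry p-value (0.05), and is
  tested against a brute-force SSE-minimizing single-knee oracle. Whether
  the 0.1 rule tests fitted or observed decrease is unstated; fitted is
  used, consistent with the segment-based phrasing.
* **dNBR under cloud gaps.** Whether consecutive *calendar* years or
  consecutive *valid* observations are differenced is unstated. The
  package differences nearest flanking valid years and assigns the value
  to the later year, mirroring compositing gaps.
* **Learning-rate schedule.** "Decreasing learning rate of 0.001 every
  epoch" is read as an initial rate of 0.001 with multiplicative per-epoch
  decay (default 0.95, configurable); the schedule form is unstated.
* **Network depth.** Kernel/width/dropout are published but not block
  count; three convolution blocks follow the original TempCNN reference
  design — the smallest faithful architecture. Reproduction is
  behavioural, not weight-level.
* **Normalization.** Inputs are standardized per band with training-set
  statistics stored in the model file; the source is silent on scaling.
* **Spatial cross-validation.** Ten iterations of independent random 90/10
  tile splits (66 tiles, 4 reserved as a holdout overfitting check) —
  repeated splits, not a 10-fold partition, matching "trained 10 times".
  Whether test tiles are drawn with or without replacement across
  iterations is unstated; splits here are independent draws.
* **Sieve semantics.** The published filter is "12-pixel sieve on a
  five-year moving window". Here a binary disturbed mask is the union of
  disturbed pixels within ±2 years of the processed year, 8-connected
  components smaller than 12 pixels are erased in the central year, and
  the pass iterates to a fixed point — a single pass is not idempotent
  because erasing one year can shrink a neighbouring year's union
  component. The "strictly smaller than 12" boundary and 8-connectivity
  follow common sieve-tool semantics.
* **Class count.** The training legend enumerates 18 classes (3 pest
  severities, 4 abrupt, 6 undisturbed covers, 5 synthetic composites);
  `n_classes` defaults to the class-scheme length and is reconciled with
  the observed labels at training time.
* **Raster format.** The environment provides no GeoTIFF bindings, so
  rasters are ESRI ASCII grids (plain text, read natively by GDAL/QGIS),
  with the published products' file naming and pass-through
  georeferencing.

## What the synthetic generator emulates — and what it does not

`simulate_trajectory()` states the package's test world:

* healthy-conifer baseline (NBR ≈ 0.67) and five other stationary cover
  baselines chosen for class separability (the source figure's band values
  are not tabulated, so these are package defaults, not calibrated);
* a linear NBR decline of the event's magnitude spread over its duration,
  realized exactly through NIR decrease and SWIR2 increase (constant
  NIR+SWIR2 sum), so stated drops are reproduced to 1e-9 at zero noise;
* class-specific visible/SWIR1 signatures (char darkening after fire, soil
  brightening after harvest, brown-needle reddening under defoliation) —
  without these the abrupt classes would be distinguishable only by
  magnitude, which no real sensor world exhibits;
* exponential recovery toward baseline (the published trajectories show
  recovery but do not parameterize it);
* i.i.d. Gaussian per-band noise (default 0.01 reflectance) and i.i.d.
  cloud gaps;
* event archetypes drawn uniformly from class ranges. Severity training
  labels follow the survey construction: the label comes from the
  *observed* dNBR at the event through the 0.1/0.15/0.25 thresholds (with
  sub-0.1 observations excluded), not from the latent archetype rate. With
  a 0.67 baseline, a linear decline at ≥ 0.1 NBR/year cannot span 15 years
  within the physical NBR range, so default severity archetypes use
  durations 2–6 years with the cumulative drop capped at 0.85; the
  published 5–15-year "gradual progression" is an ecological category, not
  a per-year spectral rate.

Not emulated: sensor harmonization artifacts, scan-line gaps, phenology,
topographic effects, spatially correlated noise, mixed pixels, or real
outbreak spatial dynamics. A green end-to-end test therefore establishes
that the pipeline recovers parameters *of this stated world* — it does not
certify accuracy on real imagery, whose validation requires the
photo-interpreted and ground-plot machinery in the validation module.

## Validation statistics

The validation module computes confusion matrices (map rows × reference
columns), per-class omission and commission errors with round-half-up
integer reporting, overall accuracy, and stratified area-adjusted
estimates: cell proportions are `sum_h W_h n_hij / n_h`; the overall
accuracy SE is the stratified binomial variance of within-stratum
agreement (no finite-population correction); per-class SEs use a
delta-method ratio approximation with the denominator treated as fixed.
With one stratum, or weights proportional to stratum sample sizes, the
estimator collapses exactly to the naive count-based metrics — a tested
invariant. A bundled 6-class benchmark matrix (1,071 photo-interpreted
points) reproduces all of its printed percentages simultaneously; note its
cells sum to 1,071 although the campaign text reports 1,073 points — the
fixture follows the printed table.

Ground-plot analysis uses the defoliated-biomass share
(%AGB defoliated = 100 × Σ AGB of defoliated coniferous trees / Σ AGB of
all trees with DBH > 9 cm), after dropping plots with deciduous-only
defoliation, more than 80% dead trees of unknown cause, or total AGB below
50 t/ha. Map extraction at validation points uses the modal code of the
3×3 neighbourhood ("9 surrounding pixels" is read as the 3×3 block
including the centre, which is what yields 9); ties prefer disturbed codes,
then the lowest code. Temporal agreement is year-set overlap, plus the
standard R².

## Numerical and degenerate-input conventions

* dNBR is decline-positive (previous minus current year).
* NBR is an error when NIR and SWIR2 are both zero; negative reflectance
  is a validation error.
* Constant series segment to a single zero-slope piece; series with fewer
  than 6 valid years are refused; all-missing series are an error.
* Training windows never place an event in the first window year (offsets
  are uniform on 1..9); inference windows impute interior missing years
  linearly and flag them.
* Prediction ties break toward the lowest class index; single-window and
  batched inference agree to 1e-6.
* All training randomness (init, shuffling, dropout) flows from one
  integer seed through a dedicated generator in compiled code, so training
  is bit-reproducible for a given seed.

## Known limitations

Segmentation at realistic noise over-detects small (~0.1) dips; the design
relies on the classifier and the sieve to absorb them, which mirrors the
production method's behaviour but means segment counts alone are not a
disturbance measure. Severity classes adjacent in dNBR remain the hardest
distinction (their end-to-end recall bound is 0.70 versus 0.90 for abrupt
classes). The stratified per-class standard errors are a delta-method
approximation, not the full design-based variance. The CLI's `map`
subcommand loads the whole scene in memory; national-scale tiling is out
of scope.
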