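---
title: "Estimating wheat biomass from UAV canopy traits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wheat biomass from UAV canopy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopybiomass)
```

## The problem

Destructive biomass cuts are the reference measurement for aboveground dry
biomass (DW~AGB~, g/m²) in wheat trials, but they are slow, costly and can
only be taken a handful of times per season. UAV imagery — five-band
reflectance orthomosaics and a canopy height model (CHM) — can be collected
at every cut and turned into plot-level *traits*: vegetation-index medians
and canopy geometry statistics. This package implements the full calibration
pipeline that links those traits to DW~AGB~: synthetic plot-scene generation
with known ground truth, trait extraction with OSAVI–Otsu canopy masking,
growth-stage classification from thermal time, recursive feature elimination
(RFE) with a PLSR base learner, multi-learner prediction models, and
within-season repeatability (w²) of the predictions from a row–column
spatial mixed model.

Because no real trial rasters ship with the package, every stage is
validated against synthetic scenes whose ground truth is known by
construction. The generator is a first-class, tested module, not a fixture.

## The synthetic generator

**Designs.** Three templates: an NVT-style row–column layout with `n_geno`
genotypes × 3 replicates; a 21-plot biomass-calibration layout (6 genotypes
× 3 densities of 75/150/225 plants/m plus a check at 150/187/112); and a
27-plot layout (7 genotypes × 3 densities of 75/150/300, unreplicated, plus
a check at all 3 densities twice — the printed description of this trial
admits more than one reading; this template reproduces the stated 27-plot
total with the check as the doubly replicated entry). Only plot *positions*
are randomized; the entry list is fixed by the template arithmetic.

**Growth.** True DW~AGB~ follows a logistic curve in cumulative thermal time
with a genotype-specific asymptote, a density-specific multiplier on the
growth *rate* (densities separate biomass accumulation early and converge at
the asymptote — a density that multiplied the asymptote itself would
contradict how sowing density acts on a closed canopy), a smooth sinusoidal
row–column trend, and an optional mean-one lognormal plot × date residual.
Canopy mean height and green cover fraction are saturating functions of
realized biomass (`1 - exp(-DW/scale)`), so with noise off both are strictly
increasing in biomass; cover declines linearly after a senescence onset
(default 1600 °C·day, full green-down over 600 °C·day).

**Scenes.** A plot raster is a two-component soil/plant mixture: each pixel
is plant with probability equal to the local green cover, plant pixels get
Gaussian-jittered heights and a plant spectrum interpolated green→senesced
by the senescence index, soil pixels get height ≈ 0 and a fixed soil
spectrum, and all bands receive small Gaussian reflectance noise. A
within-plot heterogeneity knob imposes a linear biomass gradient along the
plot so that the permanent ROI (fixed at the plot's near end) and the
per-cut precise ROIs (non-overlapping rectangles further along) can see
genuinely different canopies; the quadrat ground truth is taken at the
precise-ROI location. `coverage_mode = "exact"` replaces the Bernoulli
pixel draw with a low-discrepancy dither so that every subregion realizes
the requested cover to within a pixel — this is the fully noise-off
rendering under which extracted canopy volume is *exactly* rank-correlated
with true biomass, and it is what the monotonicity tests use.

What the generator does **not** emulate: radiative transfer, illumination
and wind artefacts, structure-from-motion reconstruction error, mixed
pixels at canopy edges, lodging, weeds. Passing tests therefore demonstrate
that the pipeline's logic is correct and well-calibrated on idealized
canopies; they do not certify accuracy values on real orthomosaics.

**Quadrat records.** `sample_biomass()` emits the raw field weights
(FW~quad~, FW~sub~, DW~sub~, area) whose reduction
`FW_quad · (DW_sub/FW_sub) / Quad_area` returns the true biomass times a
Gaussian multiplicative measurement error (default CV 0.05, a realistic
weighing/subsampling error), with the dry:fresh ratio drawn uniformly in
0.15–0.45.

## Phenology and growth stages

Trial-mean Zadoks score is modelled as a generalized additive model on
cumulative thermal time: a cubic regression spline with 10 knots, smoothing
strength by generalized cross-validation (the common default for this
fitter family; the source protocol fixes the basis but not the selector).
Thermal time accumulates `max(0, (tmin+tmax)/2 - base)` daily; the base
temperature defaults to 0 °C, the standard wheat convention — stage
thresholds are only meaningful relative to a stated base.

Stage boundaries are the smallest thermal times where the fitted curve
reaches Zadoks 50 (head emergence) and 70 (grain development), found by
bisection to 0.5 °C·day; taking the *smallest* crossing guards against
smooth wiggles. Classification is then purely by thermal time with
inclusive upper bounds: vegetative ≤ first boundary < flowering ≤ second
boundary < grain-fill, which partitions [0, ∞). The synthetic Zadoks
generator is parameterized directly by the two crossings, so
recovery of configured boundaries (e.g. 1189 and 1523 °C·day) through the
fit-and-solve cycle is an end-to-end check with known truth; with 30
observations and score noise σ = 2, the recovered boundaries sit within a
few percent (median over 20 replicates well inside ±5%).

## Trait extraction

**Registry.** 33 vegetation indices over blue/green/red/red-edge/NIR,
including OSAVI (the masking channel) and GSAVI. Only canonical forms whose
denominators cannot vanish on positive reflectances are registered, so every
index is finite wherever reflectances are positive; this is why EVI2 stands
in for EVI and there is no VARI/MTCI. The registry is data: one auditable
list, each entry a pure function of the five bands.

**Masking.** OSAVI over the ROI is thresholded by Otsu's method on a
256-bin histogram (threshold = the interior bin edge maximizing
between-class variance; ties to the lowest edge; canopy = strictly above).
A separability gate (between-class/total variance ≥ 0.75 at the chosen
threshold) guards against thresholding unimodal noise: a bare-soil or fully
closed scene has no separable second class, and its coverage is defined as
0 rather than the ~50% that raw Otsu would return on pure noise. A
well-mixed soil/plant scene scores ≈ 0.9 on this ratio, unimodal Gaussian
noise ≈ 0.64, so the gate is far from both.

**Traits.** 9 geometric: height percentiles p50/p75/p95/p98 (linear
interpolation between order statistics, the conventional default —
percentile method matters at desk-scale pixel counts and is logged here for
reproducibility); ground area below the p25/p50/p75 height percentiles
(strict inequality against the same-ROI percentile, which makes the
constant-raster case a well-defined 0; absolute m² by default with a
fraction option); canopy volume (sum of pixel heights × pixel area / ROI
area — equal to mean pixel height whenever ROI area is pixel count ×
gsd²); and OSAVI-Otsu coverage. The height standard deviation is available
behind `include_sd = TRUE` but is not part of the 9-trait contract, whose
printed total governs downstream column counts. 66 spectral: the median of
each registry index over all ROI pixels and over masked pixels only;
masked medians are `NA` at coverage 0 and flagged low-support below 10
masked pixels (a median of a handful of pixels is unstable; flagged, not
dropped). Pixel membership is center-in-polygon.

## Feature selection

Unsupervised filtering first: while any pair of columns has |r| > 0.95,
drop from the worst pair the column with the larger mean absolute
correlation to everything else (the conventional greedy heuristic; which
member to drop is otherwise arbitrary, and this choice is deterministic and
idempotent). Then RFE with a PLSR base learner: 30 resamples at 80:20
(stratified by experiment), inner tenfold cross-validation over 1..p
components at every subset size, one feature eliminated per iteration by
lowest importance. Importance is the weighted sum over components of
absolute per-component coefficients on standardized predictors, weights
proportional to the response variance each component explains. Predictors
are centered and scaled inside each training fold only — never on pooled
data — so the resampled profile is leakage-free. Ranks are aggregated as
mean elimination position with alphabetical tie-breaks; the subset size is
the smallest whose mean RMSE is within one standard error (over the 30
resamples) of the best size. Inner fold seeds derive deterministically from
(outer seed, resample index), so a profile is bit-reproducible.

The PLSR engine is SIMPLS, implemented in the package (per-component
coefficients are needed for the importance score); it is cross-checked in
the tests against an independent PLS implementation.

## Prediction models

Four learner families: PLSR (components 1..p), random forest (mtry 1..p,
minimum node size 5, variance split), polynomial-kernel SVM (degree 1–2,
C 100–1000, kernel scale 10⁻⁴–10⁻²), gradient-boosted trees (20–40 rounds,
depth 9–10, learning rate 0.1–0.3, gamma 0.7–0.9, column subsample 0.7–1).
Grids are searched under 10-fold × 10-repeat cross-validation; the winner
minimizes the mean RMSE over the 100 fold × repeat cells and is refit on
the full training set. Within the stated ranges the default grid density is
2–3 values per boosted-tree hyperparameter and all integers for
ncomp/mtry — a full 5-per-parameter product over five boosted-tree
hyperparameters under repeated CV buys no ranking information worth its
hundred-fold cost at these data sizes.

Metrics: R² = 1 − Σ(O−P)²/Σ(O−Ō)², RMSE = √(Σ(P−O)²/n), rRMSE = RMSE/Ō.
An `as_printed` audit flag computes the unnormalized variants (no `1 −`,
no `1/n`) for tracing legacy outputs; they are not the standard
definitions and are never used internally. `plsr_refined` in some result
tables of this literature denotes PLSR refit on the RFE-selected subset;
here that is simply the PLSR row of each cell, since every learner is
trained on the selected subset.

General-vs-specific comparisons train one model on all training rows and
one per level of an axis (stage or experiment), comparing test RMSE on
each level's test rows; levels under 10 rows are skipped with a warning.

## Within-season repeatability

Plot-level predictions are decomposed per experiment × cut into intercept,
random genotype effects, random row and column effects, and a 2-D
tensor-product P-spline surface (cubic marginal B-splines, second-order
difference penalty per axis — anisotropic), all variance components by
REML. The fit is expressed through `mgcv`'s penalized mixed-model
machinery, which is the same representation the SpATS family of spatial
trial models uses; on small instances the tests re-derive every component's
effective dimension from an explicitly assembled hat matrix. Marginal basis
dimension defaults to min(grid size, 10) per axis; the surface is dropped
(flagged) below a 4×4 grid where a cubic tensor basis is not
constructible.

Effective dimension of a component is the trace of its hat-matrix block.
Repeatability is w² = ED~g~/(n~geno~ − 1), clamped to [0, 1]: the genetic
component's effective dimension relative to its unshrunken (fixed-effect)
maximum. The alternative denominator "total number of observations" seen
in print cannot reach 1 even in the noiseless, fully replicated limit and
conflicts with the methodology this statistic descends from; it is kept
behind `eq6_as_printed = TRUE` for audit only. The shrinkage offset in that
denominator is absorbed as the constant 1 (intercept confounding). w² is
computed on out-of-fold cross-validation predictions: test-set predictions
would leave most plots of a cut unscored, and in-sample predictions would
inflate the genetic signal of flexible learners.

Under a true V~G~ of zero, REML variance estimates are a half-null
mixture: the typical estimate is ~0 but individual trials can show
w² up to ≈ 0.4. The tests therefore assert on medians plus a loose upper
tail, not on every seed.

## Numerical choices and degenerate inputs

- Every stochastic operation takes a mandatory seed and restores the
  caller's RNG state; derived seeds stay below 2³¹.
- Otsu on a constant raster is an error at the function level and a
  defined coverage-0 at the masking level.
- `compute_dw_agb` rejects FW~sub~ = 0 with nonzero quadrat weight,
  DW~sub~ > FW~sub~, and non-positive areas.
- The phenology solver refuses curves that never reach the target score in
  the observed range, and refuses unordered boundary pairs.
- PLSR stops early at numerically rank-deficient components; constant
  predictors are unit-scaled by convention and carry zero weight.
- Stage-cell model fits require 20+ rows; general/specific levels under 10
  rows are skipped with a warning, not silently.

## Problem sizes used by the test-suite

The suites run the study logic at desk scale, chosen as the smallest sizes
at which each property is informative: 32–64-pixel-square scenes; 2–8
experiments of 15–24 plots; RFE recovery at n = 100, p = 20 over 100
seeds; repeatability sweeps with 30 genotypes × 3 replicates over 10–20
seeds per condition; the combined-versus-single-family comparison at the
default study shape (8 experiments × 24 plots × 5 cuts). The full default
`run_study()` at 10×10 CV with all four learners is sized for minutes, not
hours, on one core.

## Known limitations

- Reflectance realism is limited to two endmember spectra plus noise;
  indices that differentiate mainly through red-edge dynamics are less
  informative here than on real canopies.
- The repeatability module assumes a single trial grid per experiment ×
  cut; multi-environment genetic correlations and pedigree information are
  out of scope.
- The 27-plot 2022 calibration template is one documented reading of an
  ambiguous printed layout.
- Real-data entry points (TIFF + GeoJSON + CSV) use plain TIFF with a JSON
  georeferencing sidecar; fully tagged GeoTIFF I/O would need a GDAL-backed
  reader.
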