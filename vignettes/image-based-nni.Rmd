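---
title: "Image-based diagnosis of plant nitrogen status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based diagnosis of plant nitrogen status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnipheno)
```

## The problem

The nitrogen nutrition index (NNI) is the established statistic for crop N
status: the measured shoot N concentration `Nt` (g/kg dry weight) divided by
the *critical* concentration `Nc`, the minimal concentration that still
supports maximal dry-matter accumulation. `NNI = 1` is optimal; below 1 the
crop is N-deficient, above 1 N is in surplus. Determining NNI destructively
(oven-drying, elemental analysis) is slow and consumes the plant. This
package implements an alternative chain for rosette-forming leafy
vegetables such as pakchoi: photograph the plant from above, segment it from
the background, summarise it into 65 colour, texture and geometry features,
and regress NNI on those features with standard machine-learning models.

The chain is:

1. **Segmentation** — excess green index band plus brightness rejection,
   then morphological clean-up (`segment_plant`).
2. **Phenotyping** — 65 features (`extract_features`).
3. **Nitrogen module** — critical-N dilution curve and NNI
   (`fit_dilution_curve`, `critical_n`, `compute_nni`, `nni_table`).
4. **Screening** — per-date one-way ANOVA across N doses; keep features
   significant at every date (`anova_screen`).
5. **Regression** — random forest, RBF support-vector regression and a
   single-hidden-layer neural network, tuned by 10-fold CV over fixed grids
   (`cross_validate`, `train_nni_model`).
6. **Evaluation** — adjusted R², RMSE, MAE, relative standard error and
   accuracy, overall and per scenario (`evaluation_report`).

A synthetic generator (`generate_trajectories`, `render_plant`,
`generate_dataset`) supplies images with *known* ground-truth NNI so that
all of the above is testable end to end.

## Segmentation

Pixels are kept when the excess green index `ExG = 2G − R − B` (computed on
raw 8-bit channels, signed, unnormalised) lies in the inclusive band
[40, 200] *and* the BT.601 grey level `round(0.299 R + 0.587 G + 0.114 B)`
is strictly below 240. The intersection is then cleaned in a fixed order:

1. morphological opening with a 3×3 square structuring element,
2. removal of 8-connected objects smaller than 1/10 of the current mask
   area,
3. filling of 4-connected background holes (complement components that do
   not touch the image border) smaller than 1/20 of the current mask area.

The reference area of each fractional filter is recomputed at the moment
that filter runs, reading the flow sequentially. Where conventions are
under-determined — band inclusivity, the strictness of the grey threshold,
kernel size and connectivity — the choices above are pinned in
`segmentation_params()` so results are reproducible; they are deliberate
decisions, not discoveries. An empty mask at any point raises a
`"no plant detected"` error rather than returning silently.

## The 65 features

* **Colour (45):** mean, *population* standard deviation, median, range and
  coefficient of variation of the nine channels R, G, B; L, a, b; H, S, V,
  computed over plant pixels only (a bright background would otherwise
  dominate every statistic). Conventions follow common 8-bit imaging
  toolchains: H on the half-degree scale [0, 180), S and V scaled to
  0–255, CIE Lab (D65) with L mapped to 0–255 and a, b offset by +128.
  A zero-mean channel reports CV = 0.
* **Texture (6):** grey-level co-occurrence features — contrast,
  dissimilarity, homogeneity, energy, correlation, angular second moment
  (with `energy = sqrt(ASM)`). Defaults in `glcm_params()` are the
  canonical configuration: distance 1, the four principal directions
  normalised per direction and averaged, 256 grey levels, symmetric
  counts. Pairs involving background pixels are excluded. A patch with a
  single grey level has no co-occurrence dispersion; its correlation is
  reported as 1 and flagged.
* **Geometry (14):** computed on the largest 8-connected component — pixel
  count as contour area, Moore-traced boundary-chain perimeter,
  bounding-box width/height, convex-hull area, minimum-area rotated
  rectangle, moment-ellipse axes (`MA = 4·sqrt(λmax)`), minimum enclosing
  circle radius (Welzl), equivalent diameter `sqrt(4A/π)`, aspect ratio,
  extent and solidity. Hull-based measures use boundary pixels expanded to
  their four corners, so a rasterised s×s square has hull area exactly
  `s²` and solidity exactly 1. `mm_per_px` (default 1, i.e. pixel units —
  no camera calibration is assumed) scales lengths and areas.

Components of fewer than 5 pixels have no stable moment ellipse; their axes
fall back to the rotated-rectangle sides and the vector is flagged.

## Dilution curve and NNI

`fit_dilution_curve` fits `ln(Nc) = ln(a) + b·ln(DM)` by least squares;
the sign of `b` is unconstrained because under frequent small N doses the
shoot N concentration can *rise* with biomass instead of diluting.
`classify_limiting` implements the operational definition of an N-limiting
treatment — more N gives significantly more biomass — as: a significant
omnibus one-way ANOVA at that date *and* at least one higher dose with
significantly greater biomass (one-sided Welch test). The comparison runs
against every higher dose, not only the adjacent one: biomass saturates
near the optimum, so the adjacent dose may sit on the plateau while a
further dose still shows the response; with the adjacent-only rule the
second dose of the emulated trial could never be classified N-limiting even
though the highest dose clearly out-grows it. Per-date labels are
aggregated by majority across dates.

NNI itself is the plain ratio `Nt/Nc`, reported half-up at two decimals,
and `classify_status` calls values within ±0.005 of 1 (those that print as
1.00) optimal. `nni_table` accepts either an explicit per-date `Nc` list —
the route used to reproduce published tables, since the exact regression
protocol behind printed `Nc` values is rarely recoverable — or a fitted
curve evaluated at the mean biomass of the non-N-limiting treatments.

One reproduction caveat: of the 24 published NNI cells carried in
`reference_nni()`, one (the unfertilised control at day 21) differs by one
unit in the second decimal from the ratio of its own published inputs
(39.07/69.16 = 0.56 versus a printed 0.57). The package computes the ratio;
the reference table keeps the printed value with the cell flagged in
`matches_inputs`.

## Screening

Features are z-scored (population SD; constant features map to 0 with a
warning) and screened by the omnibus one-way ANOVA F-test per sampling
date, treatments as groups. A feature is kept only if `p < alpha` strictly
at *every* date. `-log10(p)` is floored at `1e-300`. No multiple-testing
correction is applied across the 65 features — the all-dates rule is
itself a severe filter (under a global null the chance a feature passes six
independent dates at α = 0.05 is `0.05^6`). The published 23-feature set
(16 colour, 3 texture, 4 morphology) ships as `preset_features("paper23")`
for use without re-screening.

## Regression

The three regressors and their search grids are fixed: random forest with
300 trees and `mtry ∈ {2, 5, 8}`; RBF support-vector regression with cost
and gamma each over the 17 powers of two from 2⁻⁸ to 2⁸ (ε fixed at 0.1,
which the grid's source left unstated); a single-hidden-layer network with
decay ∈ {0, 0.1, 0.01} × size ∈ {2, 5, 9}. Data are split 75/25 (training
size rounded half up), hyperparameters chosen by 10-fold CV minimising mean
RMSE with ties broken toward the most parsimonious candidate (smallest
mtry, cost or size). One fold assignment is shared across the grid.

Two deliberate conventions:

* The network uses a **logistic output unit** by default, so predictions
  live in (0, 1). In-study NNI reaches ≈ 1.12, so the logistic output caps
  surplus predictions at 1 — visible in evaluation as a ceiling. This
  mirrors the observed behaviour of the modelling stack the package
  emulates and is switchable (`linout = TRUE`).
* Features are z-scored with **training-set statistics** re-applied at
  prediction time (a leakage guard; normalising before the split is the
  laxer alternative and is not the default).

Feature importance is permutation %IncMSE —
`100·(MSE_permuted − MSE_base)/MSE_base` averaged over shuffles — applied
uniformly to all three algorithms so scores are comparable; permuting a
constant feature is exactly 0 by construction.

## Evaluation

`compute_metrics` reports RMSE, MAE and the *adjusted* determination
coefficient of the regression of measured on simulated NNI
(`R²adj = 1 − (1 − R²)(n − 1)/(n − 2)` for the single predictor).
`agreement_metrics` reports the relative standard error — the residual
standard error of that same regression (n − 2 denominator) as a percentage
of the mean measured value — and accuracy, the Pearson correlation. Both
are invariant to affine transformations of the predictions.
`stratify_predictions` forms the scenario scopes: measured NNI > 1
(surplus), < 1 (deficient; exactly 1.00 belongs to neither and is
counted separately), and growth stages from a day-to-stage map whose
default calls the final sampling day the harvest period and everything
earlier the seedling period (both readings of "seedling" are expressible
through the map).

The surplus scope illustrates *variance attenuation*: restricting the
measured range shrinks the signal variance while the prediction error
stays put, so R² and accuracy fall even though the relative error stays
small. This is the mechanism behind poor apparent performance under N
surplus, and the package's tests verify the qualitative pattern rather
than any particular published figure.

## The synthetic generator

No image archive accompanies the study the package emulates, so the
generator stands in for the plant material. It is calibrated to the
published agronomic envelope, not to any image statistic:

* **Design:** four doses (0, 0.134, 0.163, 0.191 g N/pot) × six weekly
  sampling dates, replicated; `agronomic_design()` defaults.
* **Trajectories:** biomass grows exponentially with day, with rate and
  intercept rising (saturating) with dose, spanning ≈ 0.065–1.36 g/plant;
  the true NNI of the unfertilised control declines from ≈ 0.77 to ≈ 0.26
  while fertilised treatments sit near or a little above 1 — the published
  pattern. N concentration is then *defined* through the generator's own
  dilution curve `Nc = 75·DM^0.12` as `Nt = NNI·Nc`, so curve fitting
  downstream can recover (a, b) exactly on noiseless data
  (parameter-recovery tests). Noise is multiplicative Gaussian with
  CV = 0.05 by default, matching the 2–10% replicate scatter of the
  published growth table.
* **Rendering:** a rosette of overlapping rotated ellipses (radial
  placement with angular jitter) — the simplest leaf-shape family that
  exercises all 14 geometry features. Greenness (an affine clamp of NNI)
  drives a hue/saturation ramp from pale yellow-green (80°) to deep green
  (120°) at fixed value, emulating the chlorosis-to-dark-green gradient;
  the endpoints keep plant pixels inside the ExG segmentation band.
  Texture amplitude falls with greenness (starved plants render more
  heterogeneous) and feeds a grey-level noise field added *identically* to
  R, G and B — it perturbs co-occurrence texture but cannot move any
  pixel's ExG, keeping segmentation and texture concerns orthogonal.
  Plant size (`scale_px`, leaf count) grows with biomass; the background
  is uniform near-white grey that fails the ExG band.

What the generator does *not* emulate: specular highlights, shadows,
overlapping neighbour plants, soil or pot texture, perspective, and any
real covariance between leaf shape and N status beyond size. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
recovers known structure — not that the same accuracy would be achieved on
real photographs.

## Numerical choices and problem sizes

* Connected components: two-pass union-find in C (8-connectivity for
  objects, 4 for holes). Hole = complement component not touching the
  border.
* Reported NNI rounding: half away from zero at 2 decimals
  (`round_half_up`), matching how such tables are conventionally printed.
* Degenerate inputs are errors, not NAs: empty masks, non-positive
  biomass, single replicates in the limiting classification, fewer than 3
  points for a curve fit.
* Test problem sizes were chosen as the smallest that exercise each
  property: the segmentation suite uses 50 renders; the end-to-end model
  check uses the full 4 × 6 × 16 = 384-sample design with complete search
  grids; the ANOVA calibration uses 200 null replicates.

## Known limitations

* The renderer's colour-NNI link is exact up to rendering noise, so model
  accuracies on synthetic data are optimistic relative to field imagery.
* The logistic NN output cannot express NNI > 1; use `linout = TRUE` when
  surplus quantification matters.
* `geometry_features`' perimeter is a boundary-chain length; like any
  chain measure it differs from the continuous perimeter of smooth shapes
  by a small rasterisation factor.
* The dilution-curve stage assumes at least one treatment is non-limiting
  at the tested doses; designs where every dose is limiting fall back to
  errors rather than extrapolation.
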