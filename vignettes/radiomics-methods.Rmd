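---
title: "Radiomics outcome modeling for pleural mesothelioma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics outcome modeling for pleural mesothelioma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pleuradiomics` implements a complete FDG PET/CT radiomics outcome-modeling
chain for malignant pleural mesothelioma (MPM): image preprocessing, a fixed
1404-feature CT / 1410-feature PET catalogue, inter-observer robustness
filtering, and a prognostic Cox model builder with risk stratification.
Because MPM imaging cohorts of this kind are not publicly available, the
package ships a synthetic phantom/cohort generator that plants a known
image-derived prognostic effect, so every stage is exercised and validated
end to end on data whose ground truth is known. This vignette records the
model, the tunable parameters, and the design decisions that were genuinely
open.

## Preprocessing chain

Volumes are resampled to cubic voxels by trilinear interpolation — 3.3 mm
for CT, 5.5 mm for PET (`ct_voxel_mm`, `pet_voxel_mm`) — before any texture
analysis, so that the 3D texture operators act on an isotropic grid. Masks
follow the same trilinear rule and are re-binarized at 0.5; this behaves
more smoothly under contour transfer than nearest-neighbour sampling and is
consistent with using linear interpolation for the images. The CT analysis
mask is restricted to the closed Hounsfield window [-300, 200] HU to limit
analysis to tumor tissue; the *windowed* CT contour is what gets transferred
onto the PET grid. The window is treated as a closed interval — the bounds
themselves are tumor range — because an open reading would silently drop
boundary voxels for no physical reason.

In-mask intensities are discretized to equally spaced bins of fixed width:
5 HU for CT and 0.25 SUV for PET (`ct_bin`, `pet_bin`). The bin origin is
anchored at the in-mask minimum (`level = floor((x - min)/w) + 1`), the
common fixed-bin-size convention; discretization is therefore invariant to
adding a constant to all intensities, and the grey-level count `G` adapts to
the in-mask dynamic range.

## The feature catalogue

The catalogue is fixed and versioned: 18 shape + 17 intensity + 137 texture
features on the original image; the same 17 + 137 on each of eight wavelet
sub-band maps (1232 wavelet features); and for PET six metabolic tumor
volume features, MTV20–MTV70, the volume above 20%–70% of SUVmax. Totals:
1404 for CT and 1410 for PET. The texture block decomposes as GLCM 26 x 2
aggregations + GLRLM 16 x 2 + GLSZM 16 + GLDZM 16 + NGTDM 5 + NGLDM 16
(dependence-count percentage dropped to keep the family at 16). GLCM and
GLRLM features are reported both direction-averaged over the 13 unique 3D
directions and computed once on the direction-merged matrix; both variants
are separate catalogue entries. Feature membership follows standard IBSI
nomenclature; the counts, not the exact member identities, are the
normative constraint.

Degenerate-input conventions (all triggered routinely on small or flat
regions, so they are fixed rather than left to chance): a single grey level
gives maximal correlation coefficient 1 and missing correlation-type
features; coefficient of variation is missing at zero mean; NGTDM
coarseness/busyness are missing when their defining sums vanish, while
NGTDM contrast and strength are 0 for a flat region; a voxel without
in-mask neighbours contributes to no NGTDM cell. Percentiles use linear
interpolation between order statistics (R type 7) everywhere — intensity
percentiles, bootstrap CIs and the risk threshold alike.

Shape features are intensity-independent. Surface area and mesh volume come
from a marching-tetrahedra iso-surface at level 0.5 of the lightly smoothed
(Gaussian, 0.8 voxel) binary mask, with edge crossings linearly
interpolated and the volume obtained by the divergence theorem over the
oriented closed mesh. Meshing the raw 0/1 staircase would overestimate a
sphere's surface by ~28% and push sphericity to ~0.78; with the smoothed
field a rasterized 10 mm sphere measures sphericity ≈ 0.99. Structures
thinner than the smoothing kernel fall back to the unsmoothed field so
they never vanish. The centre-of-mass shift is defined here as the distance
between the mask centroid and the centre of its axis-aligned bounding box —
an intensity-free asymmetry measure, chosen to keep the whole shape family
independent of the intensity channel.

The wavelet stack is a one-level undecimated (stationary) separable
Coiflet-1 transform with half-point symmetric boundary handling. Band
letters are axis-ordered (x, y, z) with L/H the low/high-pass filter along
that axis; undecimated analysis keeps all eight maps congruent with the
input grid so the original ROI mask applies unchanged. The filters are
normalized so the low-pass sums to 1 (the à-trous convention) rather than
sqrt(2): sub-band coefficients then live on the intensity scale and the
modality's single fixed bin width remains meaningful on every map. Each
band map is discretized with the source modality's bin width and run
through the same intensity and texture evaluators under the original mask.

Texture-matrix construction (co-occurrence, run, zone, distance-zone,
grey-tone difference, dependence counting) is implemented in C++ for speed;
all feature formulas are evaluated in R from the matrices. The test suite
checks every texture feature against a literal brute-force R enumerator on
100 random grids to 1e-10, and checks invariance of direction-aggregated
features under 90-degree grid rotations.

## Robustness filtering

Feature stability against contour variability is measured by the
intraclass correlation across observers, computed case-wise per feature.
The variant is ICC(3,1) — two-way mixed effects, consistency, single
measure, `(BMS - EMS)/(BMS + (k-1) EMS)` — because the observers form a
fixed panel; the agreement variant ICC(2,1) is available via `type =
"agreement"`. A feature qualifies as stable when ICC is strictly greater
than 0.8; a table with zero total variance is perfectly consistent (ICC 1),
and a feature that is missing for any contour is classified unstable
without computing an ICC, since an undefined feature cannot be called
robust.

## Statistical modeling chain

Given a feature table and (time, event) outcomes, the training stage runs:

1. **Prefilter** — drop features with more than 20% missing values
   (strictly more; exactly 20% survives) or variance at or below `var_tol`
   (default 1e-8, the "low variability" cutoff left unquantified upstream);
   impute the remainder with training-cohort medians, which are frozen into
   the model for validation-time use.
2. **Horn-calibrated PCA grouping** — the number of retained components is
   the length of the leading run of correlation-matrix eigenvalues
   exceeding the mean eigenvalue spectrum of `horn_n_sim = 50` simulated
   iid-normal data sets of the same n x p (95th-percentile criterion
   available). Eigenvalues are computed via SVD of the standardized data so
   p >> n cohorts never form a p x p matrix. Each feature is then assigned
   to the retained component carrying its largest absolute loading. The
   retained loadings are varimax-rotated first: with correlated feature
   blocks of similar strength the leading eigenvalues are nearly
   degenerate, and unrotated loadings are an arbitrary rotation within
   that subspace — the rotation leaves the retained subspace untouched but
   makes the assignment well defined.
3. **Univariable screen** — per-feature Cox fit (Efron ties, standardized
   covariates), Harrell c-index of the fitted risk direction, and
   Benjamini–Hochberg q-values computed globally across all screened
   features. Global FDR control is the conservative reading of a per-group
   rule; the per-group alternative would multiply the number of informal
   tests.
4. **Per-group selection** — within each PCA group, the feature with the
   highest c-index among those with q strictly below 0.25. Groups with no
   qualifying feature contribute nothing; an empty selection is reported as
   "no model trained" rather than an error, since a null cohort is a valid
   scientific outcome.
5. **Backward AIC** — multivariate Cox on the selected features, removing
   whichever feature most lowers `AIC = -2 logPL + 2k` until no removal
   helps. Collinear starts (a failed joint fit) are treated as infinite
   AIC so redundant copies are shed rather than crashing.
6. **Risk threshold** — the 80th percentile (type-7 interpolation) of the
   training linear predictors, frozen into the model. "Predictions" are
   linear predictors of the standardized-feature Cox model; any printed
   threshold value is data-specific, not a conformance constant.

Validation scores a cohort with the frozen standardization, coefficients,
medians and threshold: Harrell c with a patient-level bootstrap CI (1000
resamples by default, seeded), risk groups at the frozen threshold (group
sizes need not be 80/20 on new data), the G-rho stratification test
(Harrington–Fleming; `rho = 0`, the log-rank test, by default) and
per-group Kaplan–Meier medians. Harrell's c counts a pair permissible when
the shorter time is an event, credits ties in the predictor 0.5, and is
oriented so a hazard-increasing predictor scores above 0.5.

Cross-validation deliberately refits only the coefficients per fold, with
the feature set fixed: the selection happened once on the full training
cohort, and the 5-fold estimate therefore carries the optimistic bias of
that sequence. This mirrors the build-then-cross-validate order of the
workflow the package implements; the report stores per-fold values so the
spread is visible. Folds are stratified by event status and redrawn
(bounded retries) if a training fold ends up event-free.

## The synthetic cohort generator

Each case is a spherical lesion (radius uniform on 12–20 mm) of mean
uptake 5 SUV over a 0.5 SUV background on a 16³ grid of 5.5 mm voxels,
with additive white noise (SD 0.15 SUV) and a within-lesion texture field:
Gaussian white noise smoothed to an 8 mm correlation length, rescaled to
unit SD and multiplied by the case's heterogeneity parameter `h`, drawn
uniformly from 0.1–1.5 SUV. Band-limited (rather than white) texture makes
intensity-variance *and* texture families respond to `h` with the
correlated structure that makes PCA grouping meaningful. Survival times are
exponential with log-hazard `beta_true * standardize(h)` and mean 16
months at the cohort average — a deliberately MPM-like scale (reported
median PFS near one year) — with independent uniform censoring on `[0, U]`,
`U` solved numerically for the target censoring fraction (default 30%).
`beta_true = 1` per SD (hazard ratio e ≈ 2.7) is the planted-effect
condition used in the end-to-end checks: a strong but realistic dominant
prognostic factor. Observer variability is emulated by a level-set shift:
the signed distance to the mask surface is perturbed by a smooth Gaussian
random field (15 mm correlation length) of RMS amplitude `magnitude_mm`,
leaving the deep interior untouched. All randomness flows from one integer
master seed through a single splitting rule (`sample.int` sub-seeds under
the master seed), so cohorts are bit-reproducible.

What the generator does *not* emulate — and what passing tests therefore do
not establish about clinical data: pleural-rind geometry (lesions are
spheres, so shape features carry no outcome signal by design), scanner
point-spread functions and reconstruction artefacts, multi-scanner batch
effects, correlated censoring, and inter-observer disagreement structure
beyond smooth boundary displacement. The pipeline's recovery of the planted
effect demonstrates the statistical machinery is sound, not that PET
texture predicts MPM survival in any particular clinic.

## Numerical choices and problem sizes

Tolerances: texture features agree with the brute-force oracle to 1e-10;
hand-worked micro-examples are asserted exactly. Degenerate risk splits
(all linear predictors equal) are flagged rather than split. Cox fits that
fail to converge or separate are flagged and treated as non-informative
(coefficient 0, p 1) so a screen never aborts on one pathological feature.
The acceptance checks run 20 planted-effect and 20 null cohorts of 72
cases with full 1404/1410-feature extraction, 100 Cox-recovery and 50
factor-recovery replicates, 100 oracle grids up to 4³, and 200 null
log-rank simulations — sizes chosen so the whole evidence chain reruns in
minutes on a single core while keeping the Monte-Carlo margins comfortably
away from their thresholds.

## Interfaces

The workflow is driven by the numbered scripts under `analysis/`
(simulate, extract, stability, model), each a thin narrative wrapper over
the exported functions that writes its tables under `results/`; the
functions themselves are the API for anything programmatic, and
`scripts/acceptance.R` reruns the headline quantities from scratch. Cohorts
are exchanged as paired NIfTI files plus an `outcomes.csv`
(`case_id,time_months,event`); features as one CSV row per case with
missing values as empty cells; the catalogue, fitted model and validation
report as JSON.

## Known limitations

The catalogue is a constrained reconstruction pinned by family counts, not
a byte-level reimplementation of any particular radiomics toolbox, and no
IBSI compliance certification is claimed. Texture is only defined on the
isotropic resampled grid (no 2D/per-slice modes). The wavelet basis and
its normalization are package choices among several common conventions.
ICC variant choice (consistency vs agreement) changes which features pass
near the 0.8 boundary. With 36 training patients and ~1000 surviving
features, the modeling chain is honest about its regime: expect "no model
trained" under the null and materially optimistic cross-validation
relative to external validation.
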