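# pleuradiomics

An R package implementing a complete FDG PET/CT radiomics outcome-modeling
pipeline for malignant pleural mesothelioma (MPM) — the setting where
patient selection for aggressive multimodal treatment hinges on prognosis,
and where quantitative image texture is a candidate biomarker. The package
covers the whole chain:

- **Imaging core** — NIfTI I/O, trilinear resampling to isotropic voxels
  (3.3 mm CT / 5.5 mm PET), the closed [-300, 200] HU tumor-tissue window,
  CT-to-PET contour transfer, and fixed-bin-width discretization (5 HU /
  0.25 SUV).
- **Feature catalogue** — 18 shape + 17 intensity + 137 texture features
  (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM) on the original image, the same
  154 intensity + texture features on each of eight undecimated Coiflet-1
  wavelet sub-bands, and six PET metabolic-tumor-volume features
  (MTV20–MTV70): exactly 1404 CT / 1410 PET features. Texture matrices are
  built in C++; every feature is checked against a literal brute-force
  enumerator.
- **Robustness** — per-feature intraclass correlation ICC(3,1) across
  repeated contours; features with ICC > 0.8 count as stable.
- **Survival modeling** — missingness/variability prefilter, PCA feature
  grouping with Horn's parallel analysis, univariable Cox screening under
  Benjamini–Hochberg FDR < 0.25, per-group best-c-index selection,
  multivariate Cox with backward AIC, 5-fold cross-validated and external
  Harrell c-indices with bootstrap CIs, an 80th-percentile risk split with
  the G-rho (log-rank) test and Kaplan–Meier medians, and SUVmax / SUVmean /
  volume baselines.
- **Synthetic cohorts** — heterogeneous lesion phantoms with a controllable
  texture parameter `h`, observer-perturbed contours, and right-censored
  exponential survival whose log-hazard is linear in standardized `h`, so
  the pipeline is testable end to end with known ground truth (the clinical
  cohorts this design targets are not public).

The model at the core: for patient *i* with selected, standardized features
*x_i*, a Cox proportional-hazards model *h_i(t) = h_0(t) exp(βᵀx_i)* is fit
by maximum partial likelihood (Efron ties); the linear predictor βᵀx_i is
the risk score, thresholded at its 80th training percentile to define risk
groups, and ranked against observed survival via Harrell's concordance
index c = P(concordant | permissible pair).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # 72 phantoms + outcomes.csv
Rscript analysis/02_extract_features.R    # 1410 features per case
Rscript analysis/03_observer_stability.R  # ICC stability report, 11 cases
Rscript analysis/04_prognostic_model.R    # train 36 / validate 36
```

The final script prints (for the default seed):

```
final model: 3 feature(s) from 6 PCA groups
  +0.575  GLRLM run entropy
  +0.402  HLL intensity skewness
  -0.441  HLL intensity mean
training 5-fold CV c-index: 0.740 (95% CI 0.613-0.834)
validation c-index:         0.775 (95% CI 0.666-0.876)
risk threshold (p80 of training linear predictor): 0.892
validation risk groups: 29 low / 7 high; G-rho p = 0.0007
median survival: 16.5 (low) vs 3.8 (high) months
baseline SUVmax     train c = 0.721, validation c = 0.768
baseline SUVmean    train c = 0.550, validation c = 0.460
baseline volume_ml  train c = 0.489, validation c = 0.647
```

Read: the screen found texture/wavelet features tracking the planted
heterogeneity effect, the backward-AIC model validates at c ≈ 0.78 on the
held-out half, and the frozen risk threshold splits validation patients
into groups with clearly different survival (log-rank p < 0.001). Exact
numbers vary with the simulation seed.

Programmatically, the same chain is three calls:

```r
library(pleuradiomics)
cohort  <- simulate_cohort(n = 72, beta_true = 1, seed = 1)
features <- extract_cohort(cohort)
report  <- run_pipeline(cohort, features = features, seed = 1)
report$validation$c
```

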