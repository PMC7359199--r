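Package: pleuradiomics
Title: FDG PET/CT Radiomics Outcome Modeling for Pleural Mesothelioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3D radiomics pipeline for paired FDG PET and CT volumes of
    malignant pleural mesothelioma: isotropic resampling, Hounsfield-unit
    windowing, CT-to-PET contour transfer and fixed-bin-width discretization;
    a 1404-feature CT / 1410-feature PET catalogue covering shape, intensity,
    six texture-matrix families and eight undecimated wavelet sub-bands, plus
    PET metabolic-tumor-volume features; inter-observer robustness filtering
    by intraclass correlation; and a prognostic-model builder combining
    principal-component grouping with Horn's parallel analysis, univariable
    Cox screening under false-discovery-rate control, multivariate Cox
    regression with AIC backward selection, cross-validated and external
    concordance indices, and percentile-based risk stratification tested with
    the G-rho family of weighted log-rank statistics. A synthetic phantom and
    cohort generator with a planted image-derived prognostic effect makes the
    whole chain testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
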