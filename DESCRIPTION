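Package: rflesion
Title: Simulation and Quantitative Assessment of Acute Radiofrequency
    Ablation Lesions in Native-Contrast Cardiac MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the acute evolution of radiofrequency ablation
    lesions in the left ventricle with native-contrast cardiovascular
    magnetic resonance. Provides a short-axis digital phantom with a
    teardrop lesion core and a growing edema rim, simulation of
    T2-prepared multi-echo and inversion-recovery image series with
    Rician noise, voxelwise three-parameter T2 mapping, reference-ROI
    standard-deviation threshold segmentation of the T2-derived edema
    and the T1-derived lesion with morphological post-processing, and
    longitudinal statistics: baseline normalization, random-intercept
    linear mixed models of volume evolution, interval-wise
    edema-to-lesion volume ratios, ROI T2 time courses, Bland-Altman
    agreement, and correlation summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    EBImage,
    RNifti,
    jsonlite,
    rlang,
    dplyr,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
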