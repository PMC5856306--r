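# rflesion

Quantitative assessment of acute radiofrequency (RF) ablation lesions in
native-contrast cardiac MRI.

RF ablation of ventricular tachycardia creates a permanent lesion core
surrounded by transient interstitial edema. The two compartments are
separable without contrast agent: the core hyper-enhances on T1-weighted
inversion-recovery (IR) imaging at long inversion times, while the edema
shows elevated T2 on quantitative T2 maps. How each region evolves over
the first ~3 hours matters clinically — edema can make an acutely
successful-looking ablation line fail once it resorbs.

`rflesion` implements the full analysis chain for studying this
evolution, together with a calibrated digital phantom that provides
ground truth for every stage:

* **Phantom** — short-axis LV (blood pool, 8 mm annulus) with a teardrop
  lesion core attached at the endocardium and an edema rim growing
  linearly in time, `V(t) = V0 (1 + g t)`; tissue T2/T1 and geometry
  calibrated to published in-vivo statistics (healthy T2 39 ms, lesion
  53 ms, edema 58 ms, 1.3 × 1.3 × 6 mm voxels).
* **Simulation** — T2-prepared multi-echo series
  (`S = PD · exp(−TE/T2)`, 4 TEs over 3–184 ms) and IR series
  (`S = PD · |1 − 2 exp(−TI/T1)|`) with Rician magnitude noise.
* **Relaxometry** — voxelwise 3-parameter fit
  `S(TE) = A·exp(−TE/T2) + C` by bounded Levenberg–Marquardt with a
  Rician noise-floor correction (σ estimated from background voxels),
  validity flags, and bilinear interpolation to the 256 × 256
  processing matrix.
* **Segmentation** — edema at `mean + 3 SD` of healthy T2, lesion at
  `mean + 2 SD` of healthy signal on the long-TI (≥700 ms) IR image,
  with morphological cleanup (closing, small-component removal, hole
  filling iterated to a fixed point); volumes, transmurality
  (depth/wall thickness), diameters.
* **Longitudinal statistics** — baseline normalization, a
  random-intercept linear mixed model
  `y = β0 + β1·t + b_animal + ε` (REML, Satterthwaite p-values),
  interval-wise edema/lesion volume ratios with one-sided tests against
  1 and Welch ANOVA, frozen-ROI T2 time courses, Bland–Altman agreement
  and correlations.

With the in-vivo model coefficients, `predict_fixed()` reproduces the
headline estimates: normalized edema volume `1.20 + 0.003·180 = 1.74 ≈
1.7×` baseline and lesion volume `1.01 − 0.0006·180 = 0.9×` baseline at
180 min post-ablation.

## Worked example

```r
library(rflesion)

cfg <- phantom_config(snr = 30)            # default: calibrated LV phantom
lab <- build_label_volume(cfg, t = 10)     # anatomy 10 min post-ablation
lab
#> <label_volume> 128x128x3 @ t = 10 min
#>   lesion 0.507 mL, edematous region 0.791 mL

series <- simulate_t2prep_series(lab, cfg, seed = 7)
map <- fit_t2_map(series, class_mask(lab, "myocardium"))
roi_mean_t2(map, class_mask(lab, "healthy"))
#> [1] 37.7                                  # configured truth: 39 ms

ref <- estimate_reference_stats(map, reference_roi_mask(lab))
seg <- segment_hyperintense(map, ref, k = 3, class_mask(lab, "myocardium"))
seg
#> <segmentation_result> 0.760 mL (75 voxels), threshold 50.38 (k = 3)
```

The segmented T2-derived edematous region (0.760 mL) recovers the
phantom's ground-truth 0.791 mL region within 4% at SNR 30; the
threshold 50.4 ms is the measured healthy mean plus three measured SDs.

```r
tbl <- simulate_lmm_study(seed = 1)        # 13 lesions / 11 animals study
fit <- fit_lmm(tbl)
fit
#> <lmm_fit> normalized_volume ~ t_min + (1 | animal_id), REML
#>   intercept 1.1764 +/- 0.0497 (p = 2.29e-23)
#>   slope     0.00349 +/- 0.00043 per min (p = 4.51e-11)
#>   var(animal) = 0.008398, var(resid) = 0.02096; 13 lesions / 11 animals / 65 obs
predict_fixed(fit, 180)
#> [1] 1.81
```

One simulated study drawn at the in-vivo design (true slope 0.003/min,
true intercept 1.20) is fitted here; the estimated slope 0.0035 ± 0.0004
and the 180-min prediction 1.81× baseline sit within sampling error of
the truth — the parameter-recovery tests repeat this 200 times.

`run_pipeline(pipeline_config(...))` chains the stages end to end and a
thin CLI (`inst/exec/rflesion`) exposes `simulate`, `fit-t2`, `segment`,
`analyze` and `pipeline` subcommands.

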