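---
title: "Quantifying acute RF ablation lesions in native-contrast cardiac MRI: models and methods"
author: "rflesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute RF ablation lesions in native-contrast cardiac MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflesion)
```

## The problem

Radiofrequency (RF) ablation of ventricular tachycardia aims to create a
permanent necrotic lesion at a critical site of the re-entry circuit. The
thermal insult also produces a surrounding halo of interstitial edema —
transient injury that can mimic successful ablation acutely and resolve
later, contributing to arrhythmia recurrence. Native-contrast
cardiovascular MR can separate the two tissue compartments during the
procedure itself: the permanent lesion core hyper-enhances on
T1-weighted inversion-recovery imaging at long inversion times (its T1
is shortened by methemoglobin formation), while the edematous halo shows
elevated T2 on quantitative T2 maps.

`rflesion` implements the full quantitative chain for studying how these
two regions evolve in the first hours after ablation: a digital
short-axis left-ventricular phantom with a time-evolving injury,
simulation of the two native-contrast acquisitions, voxelwise T2
mapping, threshold-based segmentation of both regions, and longitudinal
mixed-effects statistics of the segmented volumes. Because no raw
in-vivo data of this kind are publicly deposited, the phantom is the
package's test bed: every stage can be validated against known ground
truth that is itself calibrated to published in-vivo summary statistics
(healthy myocardial T2 39 ms, baseline edema volume 0.77 mL, baseline
lesion volume 0.48 mL, normalized edema growth 0.003/min, and so on).

## The phantom

`phantom_config()` describes a circular short-axis LV: a blood pool of
radius 25 mm inside a myocardial annulus reaching 33 mm (an 8 mm wall),
sampled at 1.3 × 1.3 mm in-plane with three adjacent 6 mm slices — the
acquisition geometry used intra-procedurally. Tissue classes carry
(T1, T2, proton density): blood (1600, 250, 1.2), healthy myocardium
(1100, 39, 1.0), lesion core (800, 53, 1.0) and edema rim
(1150, 58, 1.0). Only the healthy T2, the injury T2s, and the
lesion-vs-healthy T1 *ordering* are constrained by in-vivo
measurements; the remaining T1s and proton densities are plausible
1.5 T values and nothing downstream depends on them beyond that
ordering.

The lesion core is a teardrop: a half-ellipsoid attached at the
endocardial border with its long axis along the local radial direction,
parameterized by angular position, surface width, and depth as a
fraction of wall thickness (default 0.52, the in-vivo initial
transmurality). An annular-sector shape with a closed-form volume is
included for validating the rasterizer against analytic geometry
(`lesion_spec(shape = "sector")`).

The ground-truth edematous region (lesion ∪ rim) grows linearly,
$V(t) = V_0\,(1 + g\,t)$ with $g = 0.003$/min by default, realized
geometrically: the rim is the set of annulus voxels nearest to the
lesion core, first wetting the lesion's in-plane boundary (edema forms
at the lesion interface) and then thickening outward by 3D distance.
Allocation ties are spread by a deterministic low-discrepancy hash so
no slice is systematically starved when the rim budget is tight. This
keeps the region connected, always encompassing the core, and accurate
to one voxel against the target volume; growth by geometry (rather than
by intensity change) keeps segmentation accuracy separable from
simulation fidelity. A request that cannot fit in the annulus, or that
is smaller than the core, is a hard error rather than a silent
truncation.

One geometric consequence is worth knowing: at the in-vivo baseline
volumes (a 0.77 mL region around a ≈0.5 mL core) the rim holds fewer
voxels than the core's full boundary layer, so the true rim is a
*partial*, one-voxel-thick shell. This is the regime the segmentation
has to survive, and it drives several defaults below.

## Signal simulation

T2-prepared imaging follows the preparation decay
$S(TE) = PD \cdot e^{-TE/T_2}$ at the four echo times used in vivo
(3, 25, 75, 184 ms); inversion recovery follows the simplified
magnitude signal $S(TI) = PD \cdot |1 - 2 e^{-TI/T_1}|$, under which the
short-T1 lesion core is brighter than healthy myocardium for TIs beyond
roughly 700 ms (the balanced-SSFP readout, spiral k-space sampling,
motion and banding are deliberately out of scope). Noise is Rician —
the magnitude of the complex signal after adding independent Gaussian
noise to each channel — with the channel σ defined as the healthy
myocardium TE = 0 signal divided by the configured SNR. Rician rather
than Gaussian noise matters here because the long-TE tail of the decay
sits at the noise floor. Both simulators are deterministic given a
seed. The injury T2s can follow a step schedule over the post-ablation
analysis windows (lesion 53 → 55 → 53 ms and edema 53 → 58 → 56 ms over
0–60, 60–80, 80+ min; `default_t2_schedule()`) to emulate the measured
transient T2 rise.

## T2 mapping

`fit_t2_voxel()` fits the three-parameter model
$S(TE) = A\,e^{-TE/T_2} + C$ by bounded Levenberg–Marquardt least
squares (analytic Jacobian, log-linear initialization on the
offset-subtracted signal, $A \ge 0$, $T_2 \in [1, 500]$ ms,
$C \ge 0$). Voxels with no identifiable decay — non-decreasing signal,
a non-negative log-linear slope — or with a relative residual above
0.25 are flagged invalid, never given a default value. The offset
exists to absorb the magnitude noise floor; since the floor is known
given σ, `fit_t2_map()` first estimates σ from background (air) voxels
via the Rayleigh second moment and applies the classical second-moment
correction $\hat S = \sqrt{\max(S^2 - 2\sigma^2, 0)}$ before fitting.

Two numerical properties of this estimator shape the package's
protocol, both established against an independent dense grid-search
oracle (T2 grid at 0.1 ms, amplitude and offset solved exactly per grid
point):

* The solver finds the global constrained least-squares optimum: it
  agrees with the oracle within 1 ms on ≥95% of random noisy draws at
  SNR 30 (a standing test).
* With only 4 echoes, *any* estimator of this model — global least
  squares, Rician maximum likelihood, and second-order bias-corrected
  variants were all measured — under-reads T2 by ≈4% at SNR 30 on the
  acquisition grid. This is a small-sample property of the estimation
  problem, not a solver defect. It shrinks below 1.5% across
  T2 ∈ [30, 70] ms when images are first interpolated to the 256 × 256
  processing matrix (`interpolate_series()`), which averages
  independent voxel noise, and that is the route used for ROI T2
  statistics.

`interpolate_to_matrix()` performs the bilinear interpolation with the
voxel spacing rescaled so physical extent is preserved; constants and
integrals are preserved (tested), and a nearest-neighbour mode handles
label masks.

## Segmentation

Both injury regions are delineated by reference-ROI thresholds, exactly
as in the intra-procedural analysis: the T2-derived edematous region at
`mean + 3·SD` of healthy-myocardium T2, and the T1-derived lesion at
`mean + 2·SD` of healthy signal intensity on the first IR image with
TI ≥ 700 ms. The reference ROI is placed automatically as a 60° sector
of the annulus diametrically opposite the lesion angle
(`reference_roi_mask()`), replacing the operator of the semi-automatic
in-vivo workflow; `reference_stats()` lets a known spread (e.g. the
in-vivo 5 ms healthy T2 SD) be injected when a noiseless phantom would
otherwise measure SD = 0.

Morphological cleanup is applied per slice and iterated to a fixed
point, which guarantees idempotence by construction:

1. **Binary closing** (diamond, radius 2 by default for the edema
   channel). At SNR 30 the suprathreshold rim is a one-voxel-thick
   partial shell and per-voxel T2 noise punches gaps in it; the closing
   bridges them so that hole filling can operate. The lesion channel
   uses no closing: the core is compact, and at the more liberal 2 SD
   threshold a closing would fuse scattered noise voxels into
   components large enough to survive the next step.
2. **Small-component removal** (8-connected per slice, < 5 voxels),
   the denoising step. An *opening* is config-exposed but disabled by
   default — at baseline the rim is about one voxel thick and a
   radius-1 opening erases it entirely, which is why component removal
   plays the denoising role instead.
3. **Hole filling.** A rim around an endocardially-attached teardrop
   does not strictly enclose the core (the cavity opens onto the blood
   pool), so classical flood-fill hole filling never triggers. Holes
   are instead defined as connected components of the analysis region,
   outside the mask, that are disconnected from the region's largest
   remaining body — which captures the enclosed core while preserving
   outer borders, and is a no-op on empty masks.

Volumes are voxel count × voxel volume, exactly, with no partial-volume
weighting. Segmentation and volumes are computed **on the acquisition
grid**: the phantom's tissue is piecewise constant, so interpolating
first would only manufacture artificial partial-volume mixtures — at
the 2 SD IR threshold, boundary voxels with as little as ~23% lesion
content cross the threshold, roughly doubling small lesion volumes.
Real acquisitions carry a genuine point-spread and may prefer the
interpolate-first workflow, which `run_pipeline(interp_matrix = c(256L,
256L))` still provides.

Derived scalars: transmurality is lesion depth from the endocardial
border divided by wall thickness, measured along the radial ray through
the mask's in-plane centroid angle with a half-voxel edge correction,
reported per slice and as the across-slice maximum; diameter is the
maximum pairwise in-plane extent of mask voxel centres plus one voxel.

## Longitudinal statistics

Volumes are normalized per lesion and contrast to the earliest
post-ablation measurement (times counted from the start of ablation;
ties broken by row order, with a message). Temporal evolution is
modelled with a linear mixed model,
$$y_{it} = \beta_0 + \beta_1 t + b_{a(i)} + \varepsilon_{it},\qquad
  b_a \sim N(0, \sigma_a^2),$$
fit by REML via `lmer` with a random intercept per animal — lesions
cluster within animals, and baseline normalization already anchors each
series at 1, so no random slope is used. Satterthwaite p-values come
from `lmerTest`. The fit refuses degenerate designs (a single animal,
fewer than 3 lesions, fewer than half the lesions with repeated
imaging) rather than returning silently unstable estimates.
`predict_fixed()` gives the population prediction $\beta_0 + \beta_1
t$; with the in-vivo coefficients this reproduces the headline
estimates — edema $1.20 + 0.003 \times 180 = 1.74 \approx 1.7\times$
baseline and lesion $1.01 - 0.0006 \times 180 = 0.90\times$ baseline at
180 min.

Edema-to-lesion volume ratios are formed within the three analysis
windows used in vivo — 0–25, 60–80 and 80–185 min, with the 25–60 min
gap respected, not bridged — pairing each lesion's two contrasts
nearest-in-time within the window (the closest pair when several
observations fall inside). Each window gets mean, SD, a 95% t-interval
and a one-sided t-test of ratio > 1; windows are compared by Welch
ANOVA (the variance-equal variant was not specified in vivo, so the
robust one is used). Intervals with fewer than two pairs are excluded
with a message.

ROI T2 time courses (`roi_t2_timecourse()`, `t2_timecourse_stats()`)
track three frozen regions: the healthy reference sector, the baseline
T1-derived lesion, and the largest segmented edematous region *minus*
the lesion ROI — the two injury ROIs are reported separately, and since
edema always encompasses the lesion, leaving the core in would
double-count its lower T2 into the edema trace. Paired t-tests compare
intervals within regions and regions against healthy tissue.

Method agreement is summarized by Bland–Altman bias and 95% limits of
agreement (`bland_altman()`), with Pearson (plus regression line) and
Spearman correlations (`correlate_volumes()`); degenerate inputs are
flagged, not errors.

For parameter-recovery experiments, `simulate_lmm_study()` draws
studies directly from the random-intercept model at the in-vivo design
(13 lesions in 11 animals, ~5 times in 10–180 min, animal SD 0.1,
residual SD 0.15); 200 such studies recover the 0.003/min slope within
two Monte-Carlo standard errors with ≥90% CI coverage (a standing
test).

## Study generation and the pipeline

`generate_study()` builds multi-lesion studies: lesions assigned
cyclically to animals, per-lesion imaging times drawn with a baseline
in 5–15 min (the in-vivo median baseline was 10 min), and per-lesion
true volumes drawn from lognormal distributions moment-matched to the
in-vivo means and SDs (0.77 ± 0.55 mL edema, 0.48 ± 0.23 mL lesion).
Volumes are positive and the in-vivo SDs are large relative to the
means, which rules out a normal draw without truncation; the default
draw is *stratified* (the n mid-probability quantiles), so a 13-lesion
study's sample mean sits on the target mean without Monte-Carlo drift —
appropriate when calibrating a small synthetic study to published
summary statistics; fully random draws remain available. The teardrop
width is calibrated per lesion by bisection against the rasterized
volume, and `edema_ratio` can pin the true baseline edema-to-lesion
ratio exactly (used for ratio-recovery runs at the in-vivo early-window
value of 2.1).

`run_pipeline()` chains simulate → fit → segment → analyze into one
deterministic run (identical master seed ⇒ byte-identical report JSON),
with optional NIfTI/CSV/JSON artifacts and a thin command-line wrapper
(`inst/exec/rflesion`) exposing the stages as subcommands.

## What the phantom does and does not establish

Passing tests on this phantom demonstrate that the *analysis chain* is
correct: exact parameter recovery without noise, known noise behaviour
at SNR 30, segmentation that recovers calibrated truth volumes, and
unbiased mixed-model estimation at the study design used in vivo. The
phantom deliberately omits acquisition physics (point-spread, motion,
banding, spiral trajectories), diffuse edema borders (tissue classes
are crisp, where in-vivo edema fades into the threshold), catheter
artifacts, and operator interaction — so test results here do not
certify performance on clinical images, where the diffuse-border
regime in particular makes intensity thresholds less robust at late
time points.

Known limitations worth restating: the 4-echo, 3-parameter voxelwise
fit under-reads T2 by ≈4% at SNR 30 on the acquisition grid (an
estimator property shared by the global-LS oracle and Rician MLE, and
the reason ROI statistics use the interpolated processing matrix); the
one-voxel-thick baseline rim means noiseless thresholds with an
injected in-vivo SD cannot fully enclose the core in every slice at the
tightest baseline geometry; and wall swelling (8 → 11 mm in vivo) is
not modelled geometrically by default.

## Problem sizes used by the standing checks

The test suite and the acceptance script run phantoms at 64–128² × 3
voxels, studies of 9–13 lesions at one to five time points, and 200
replicate mixed-model simulations; these sizes were chosen as the
smallest at which every recovered quantity is stable against its
tolerance (ROI means to fractions of a millisecond, volume means to a
few percent, slope recovery to two Monte-Carlo standard errors).
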