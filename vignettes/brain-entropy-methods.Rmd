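---
title: "Image-based brain entropy: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based brain entropy: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainentropy)
```

## The measure and its assumptions

`brainentropy` operationalises "brain entropy" (BEN) as the Shannon entropy
of the pixel-intensity distribution of a rendered activation map — an ICA
component overlay exported as an RGB image. The analysis assumes:

1. **The rendering convention is known.** Activation is drawn in blue,
   artifactual signal in red, brain tissue in white/grey, everything else in
   a background colour. Segmentation assigns each pixel to the *nearest*
   reference colour in Euclidean RGB distance. This is a declared substitute
   for whatever thresholding the original rendering software used: only the
   five reference colours are specified by the convention, so nearest-colour
   classification is the minimal assumption, and the reference colours are
   user-overridable (`default_color_profiles()`) for other renderers.
2. **Only retained pixels are informative.** Background dominates any
   overlay image and would swamp the histogram, and red signals are
   explicitly artifacts; both are excluded before the histogram is formed.
   Entropy is therefore computed over white + grey + blue pixels only.
3. **One scalar intensity per pixel.** The 256-bin histogram needs a single
   0–255 value per retained pixel. RGB is collapsed by BT.601 luminance,
   `round(0.299 R + 0.587 G + 0.114 B)` — the standard 8-bit convention.

With `p_i` the normalised bin probabilities, `H = −Σ p_i log2 p_i` (with
`0·log 0 = 0`) lies in `[0, 8]` bits for 256 bins. BEN is `H / 8`, so it is
dimensionless in `[0, 1]` and comparable across image sizes. Raw bits are
always reported alongside (`image_ben()$entropy_bits`; the pipeline's
`--no-normalize` switch runs the statistics on bits), because the `[0, 1]`
scale of published group means is consistent with — but does not prove —
division by the 8-bit maximum.

A subject contributes two closely matched sequential component images; the
subject-level BEN is the arithmetic mean of the two per-image values. Which
two images "match" is a manual, aesthetic judgement in practice, so the
package takes the images as given input (the synthetic generator emits
exactly two per subject). A subject with an image yielding zero retained
pixels is flagged *excluded* rather than failing the run, mirroring how
participants without meaningful visual activation are dropped from group
analyses; exclusions are listed in the run report and log.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| reference colours | 8-bit RGB | black/white/grey/blue/red at (0,0,0), (255,255,255), (128,128,128), (0,0,255), (255,0,0) | maximally separated; the convention names colours, not RGB values |
| tie-break order | — | background < white < grey < blue < red | deterministic classification of exactly equidistant pixels |
| histogram bins | intensity levels | 256 (0–255) | 8-bit grayscale support |
| normalisation | — | ÷ log2(256) = 8 | maps entropy onto `[0, 1]` |
| `images_per_subject` | count | 2 | two matched sequential images per subject |
| `intensity_heterogeneity` | gray levels (SD) | 8 | tissue-intensity dispersion; the entropy dial |
| `noise_amplitude` | RGB units | 2 | sub-margin pixel noise for realism; small enough that the achievable BEN range spans published group means |
| t-test variant | — | pooled variances | the default row of standard statistical software; Welch available |
| chi-squared | — | no continuity correction | the uncorrected Pearson statistic is what a 20/5 vs 8/11 table's printed 6.699 corresponds to |
| coding | — | male = 1, female = 2; control = 1, ADHD = 2 | determines the *sign* of phi and point-biserial r; chosen so a male-dominated patient group and higher-entropy controls both give negative correlations |

## What the synthetic generator emulates — and what it does not

`generate_component_map()` emits a post-ICA overlay directly: an elliptical
brain of achromatic tissue pixels, Gaussian-blob blue activation confined to
the lower ("occipital") third, and red speckle elsewhere in the brain.
Entropy is location-invariant, so the spatial layout is cosmetic; what is
controlled is the *intensity distribution*. Tissue gray levels are drawn as
`base_intensity + heterogeneity · N(0, 1)`, rounded, and kept a guard band
away from the class decision boundaries (near 64 between background and
grey, near 191.5 between grey and white) so that rounding plus sub-margin
RGB noise can never flip a pixel's class — segmentation recovers the
generator's ground-truth labels exactly, which the test suite asserts on 100
seeded maps. Pixels far above the grey/white boundary are *intended* as
white, so bright tissue naturally produces all three retained classes.

Two degenerate anchors follow from the construction: with heterogeneity 0,
noise 0 and no activation, every retained pixel is identical and BEN is
exactly 0 (a single occupied bin); with activation present, blue pixels sit
at a different luminance (≈ 29) than grey tissue (128), so a second bin is
occupied and BEN is positive even at zero heterogeneity.

`generate_cohort()` draws each subject's target BEN from a normal at the
configured group mean/SD truncated to (0, 1) (published tables report only
mean ± SD, and normalised entropy must stay in the unit interval), assigns
ages from range-truncated normals, fixes the gender counts exactly, and
generates each subject's images at the dispersion that the calibration curve
maps to the subject's target. Defaults reproduce the published study
conditions: 25 ADHD (20 male / 5 female, ages 20–50, BEN 0.56 ± 0.14)
versus 19 controls (8 male / 11 female, ages 18–46, BEN 0.64 ± 0.11). The
control group is 19 because that is the composition of the realised analysis
table (one recruited participant was excluded); `follow_recruitment = TRUE`
switches to the recruitment-stage 20 (8 male / 12 female).

The generator does **not** simulate BOLD time series, head motion,
preprocessing, the ICA decomposition, anatomical structure, or the manual
selection of the visual component. Passing tests therefore demonstrate that
the *measurement and statistics pipeline* is correct and well calibrated on
images satisfying the colour convention — not that real fMRI overlays meet
that convention, nor anything about the physiology behind group differences.

## Calibration

Mean BEN is monotone non-decreasing in the dispersion parameter over the
searched range `[0, 60]` (checked empirically by the property suite, and
optionally at call time via `verify_monotone`). `calibrate_heterogeneity()`
bisects on the dispersion until the mean BEN of a seeded map sample is
within ±0.02 of the target, and errors naming the achievable range when the
target lies outside it — the range floor is set by the residual entropy of
pixel noise plus activation, the ceiling by the guard-banded gray-level
support (roughly 0.27–0.90 for the default map). For cohorts, a 17-point
`calibration_curve()` is computed once and inverted by linear interpolation;
per-subject targets outside the curve's range are clamped to its ends. The
realised subject BEN tracks the drawn target with mean absolute error below
0.01 in the test suite, so cohort-level accuracy is dominated by the
configured between-subject SD, as it should be.

## Numerical choices and conventions

- **Intensity indexing**: bins are the 256 8-bit levels 0–255 (1-based
  labels 1–256 denote the same levels).
- **Ties in classification** break by the fixed canonical class order, so
  results are reproducible across platforms.
- **Mann–Whitney U** is reported for the first (ADHD) sample with the
  tie-corrected normal-approximation Z and no continuity correction, two
  sided. The sign of Z therefore says which group ranks higher; software
  that always computes Z from the smaller rank sum prints the same magnitude
  with a negative sign.
- **p-values** are two-sided throughout. Correlation p-values use
  `t = r√(n−2)/√(1−r²)` with `n − 2` degrees of freedom.
- **Analytic t-test power** uses the noncentral t with the pooled-SD effect
  size — the textbook power of the pooled test that is actually run. (At the
  published sizes and SDs this is ≈ 0.52 at α = 0.05, matching Monte-Carlo
  rejection frequencies; the common shortcut of plugging the unequal-variance
  standard error into the noncentrality overstates power by ≈ 0.03 here.)
- **Determinism**: every stochastic routine takes an explicit seed, derives
  sub-seeds below 2³¹ for per-image streams, and restores the caller's RNG
  state. Identical configuration + seed reproduces images and CSV outputs
  byte for byte.
- **Degenerate inputs**: empty retained masks raise "no retained pixels" at
  the histogram (and mark the subject excluded at the aggregation level);
  zero-margin 2×2 tables, single-group correlations and groups smaller than
  two subjects raise named errors rather than returning NaN.

## Problem sizes used by the test and acceptance suites

Synthetic maps are 64 × 64 (32 × 32 in unit tests): large enough that
per-map BEN is stable to ≈ 0.01 yet cheap enough to generate hundreds of
maps per run. The calibration checks use 6 seeded cohorts of 50 subjects per
group (300 per group in total, standard error ≈ 0.008 on a group mean), the
segmentation round-trip uses 100 seeded maps across a spread of dispersions,
and the power comparison uses 2000 Monte-Carlo replicates (standard error
≈ 0.011 on the rejection frequency).

## Known limitations

- Published per-subject values are not available, so rank-based statistics
  (the printed Z values) and the realised BEN–group correlation can only be
  checked procedurally, not numerically; only quantities fully determined by
  printed counts (the 2×2 chi-squared and phi) are reproduced exactly.
- The `[0, 1]` scale of published BEN values is consistent with several
  normalisations (division by 8, restricted intensity support, …); the
  package adopts division by 8 and always exposes raw bits for audit.
- Nearest-colour segmentation is exact for the generator's convention but
  only an approximation for arbitrary renderers with gradients or
  anti-aliasing; override the colour profiles and inspect the label-map
  audit images when applying it to real exports.
- Blue activation pixels occupy the low-luminance bins, so activation
  fraction and entropy are mildly coupled; calibration absorbs this, but
  comparisons across very different activation fractions should be made at
  matched segmentation settings.
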