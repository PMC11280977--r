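---
title: "Methods: fat-fraction repeatability and reproducibility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fat-fraction repeatability and reproducibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrepro)
```

## The problem

Bone metastases of prostate cancer replace fatty marrow with cellular tumor,
which lowers the marrow fat fraction (FF%) measured by Dixon MRI. FF% rises
again as lesions respond to treatment and fatty marrow is restored, making it
a candidate imaging biomarker of response. Before a biomarker can be used to
track change, its measurement error must be characterised: how much does the
value move when the same reader re-segments the same lesion (repeatability),
and when a different reader segments it (reproducibility)? `ffrepro`
implements that agreement analysis end to end, together with a synthetic
imaging substrate that makes every stage testable against known ground truth.

The measurement chain is:

1. **FF% map** — from Dixon fat-only (FO) and water-only (WO) volumes,
   \(\mathrm{FF\%} = 100 \cdot \mathrm{FO} / (\mathrm{FO} + \mathrm{WO})\).
   Voxels with zero total signal carry no information and are flagged
   invalid rather than zeroed. Clinical FF maps circulate in two intensity
   dialects (values scaled by 100 or by 1000); `normalize_ff_scale()`
   divides by the declared dialect or, when unknown, infers it: a volume
   whose 99.9th percentile of valid values exceeds 110 is treated as
   per-mille. The percentile rule tolerates a few noisy super-100 voxels; a
   declared dialect always wins over inference.
2. **Lesion bookkeeping** — lesions are classified *small* (< 10 mm) or
   *large* (>= 10 mm) by their maximal axial diameter, operationalised as the
   largest pairwise distance between in-plane voxel centers on any single
   axial slice (the caliper measurement a radiologist would make; the
   convex hull makes this exact and cheap). Single-slice measurements use
   the representative slice, the one with the largest cross-sectional area,
   with ties broken deterministically toward the inferior index. Lesions
   whose segmentation spans a single slice are ineligible for volumetric
   measurement.
3. **ROI preprocessing and features** — the FF map is resampled to
   3 × 3 × 3 mm (trilinear for intensities, nearest-neighbour for masks),
   intensities normalised to percent, masked voxels pooled, and a single
   pass removes voxels more than 3 sample standard deviations from the
   sample mean. First-order features follow the standard (IBSI-consistent)
   definitions; entropy and uniformity use a fixed 64-bin histogram spanning
   the sample range.
4. **Agreement statistics** — described below, mirroring the structure of a
   two-reader study in which reader 1 segments every lesion twice and
   reader 2 once.

## Agreement model

All reliability estimates use the one-way random-effects, single-measure,
absolute-agreement intraclass correlation, ICC(1,1). For subject \(i\) and
observation \(j\),

\[ y_{ij} = \mu + b_i + e_{ij}, \qquad b_i \sim N(0, \sigma_b^2),\quad
   e_{ij} \sim N(0, \sigma_w^2), \]

\[ \mathrm{ICC} = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2}
   \;\widehat{=}\; \frac{MS_B - MS_W}{MS_B + (k-1) MS_W}. \]

The one-way model charges any systematic reader shift to the error term, so
it measures *absolute* agreement, not mere consistency. Confidence limits
use the exact F-based (Searle) interval: with \(F = MS_B/MS_W\),
\(F_L = F / F_{1-\alpha/2;\,n-1,\,n(k-1)}\) and
\(F_U = F \cdot F_{1-\alpha/2;\,n(k-1),\,n-1}\), each mapped through
\((F^*-1)/(F^*+k-1)\). The model choice pins down the estimator but not the
interval; the exact F interval is the standard companion for the one-way
model. Estimates are banded as
poor (< 0.5), moderate ([0.5, 0.75)), good ([0.75, 0.9]) and excellent
(> 0.9); the boundaries 0.75 and 0.9 are assigned to "good" because only
values strictly above 0.9 are called excellent.

Complementary statistics:

* **Bland–Altman**: bias = mean paired difference, limits of agreement
  bias ± 1.96·SD of differences, bias CI from the t distribution.
* **Within-subject SD**: \(\sqrt{MS_W}\), i.e. the square root of the mean
  per-subject sample variance.
* **Levene comparison of size classes**: with two repeats per subject, each
  subject contributes one dispersion score \(|y_{i1}-y_{i2}|/\sqrt2\) (an
  unbiased-scale estimate of \(\sigma_w\)); the classic Levene test is then
  a one-way ANOVA of these scores across the small/large groups. With
  \(k=2\) the subject-level mean and median coincide, so the mean-centered
  (Levene) and median-centered (Brown–Forsythe) variants are identical and
  no separate option is exposed.
* **Slice–volume correlation**: Spearman's rho (average ranks for ties) on
  the pooled three measurements per lesion, with a percentile bootstrap CI.
  The replicate count defaults to 2000; bootstrap CIs are deterministic
  under a fixed seed.
* **Sample size**: the Walter–Eliasziw–Donner approximation
  \(n = 1 + \frac{2k\,(z_{\alpha}+z_{\beta})^2}{(k-1)\,(\ln C_0)^2}\) with
  \(C_0 = (1+k\theta_0)/(1+k\theta_1)\), \(\theta = \rho/(1-\rho)\), rounded
  up. \(\alpha\) is interpreted two-sided by default because the one-sided
  variant yields a materially smaller cohort (26 vs 33 at
  \(\rho_0 = 0.75, \rho_1 = 0.9, k = 2\)); both options are exposed.

```{r sample-size}
walter_sample_size(rho0 = 0.75, rho1 = 0.9, k = 2, alpha = 0.05, power = 0.8)
```

## The synthetic phantom and what it does (not) emulate

No public imaging archive accompanies this kind of reader study, so the
package ships a generator whose defaults define the simulated study
conditions:

* **Anatomy**: per subject, a cropped 44 × 44 × 20 voxel field of view at
  1 × 1 × 3 mm around two ellipsoidal focal lesions — one small (in-plane
  semi-axes 2.6–4.4 mm) and one large (6.5–9 mm) — embedded in marrow with
  FF 70 ± 5 %. Lesion FF is drawn per subject around 16 % with a
  between-subject SD of 5 % (the population spread that gives the ICC its
  denominator), plus 2 % voxelwise heterogeneity, a 1 mm Gaussian interface
  blur (partial-volume band) and 2 % voxel noise. A whole-body volume would
  add nothing to the agreement statistics, so only the lesion neighbourhood
  is simulated.
* **Signal model**: a constant total Dixon signal per voxel is split as
  fat = S·f/100, water = S·(1−f/100), so the FF formula recovers the
  generated field exactly in the noise-free limit. The generated FF field
  is truncated to [0, 100] to keep both channels non-negative. There is no
  MR physics: no coil or bias fields, no chemical-shift artefacts, no
  fat–water swaps, no DWI.
* **Readers**: a segmentation is the ground-truth mask whose signed
  distance function is shifted by a smooth Gaussian random field
  (SD 1 mm, correlation length 3 mm) plus a systematic bias, then
  re-thresholded and restricted to the largest connected component. On a
  1 × 1 × 3 mm grid the signed distance is quantised at the voxel scale, so
  sub-voxel displacement SDs almost never flip a voxel — the 1 mm default
  is the smallest magnitude that produces realistic repeat-to-repeat
  variability. Reader 2 carries a 0.9 mm dilation bias (tends to include
  the bright marrow interface), which is what separates inter-reader from
  intra-reader agreement; the magnitude was chosen so the intra > inter
  ordering holds in essentially every simulated study at n = 34. Both
  readers pick the second-largest slice with probability 0.15, emulating
  blinded independent slice choice.
* **Design**: reader 1 segments twice, reader 2 once. Intra-reader cells
  compare reader 1's repeats; inter-reader cells compare the mean of reader
  1's repeats against reader 2 (for mean FF%) or reader 1's first repeat
  against reader 2 (for features, whose signed values should not be
  averaged). Lesions with any single-slice segmentation are excluded from
  volumetric cells, which keeps every analysis cell balanced.

Because reader variability in real studies arises from perception and
anatomy rather than from a stochastic boundary field, the simulated ICC
*magnitudes* are not calibrated to any particular cohort; what the phantom
reproduces — and what the acceptance simulations check — are structural
properties: intra-reader agreement exceeding inter-reader agreement in every
cell, higher within-subject variance for small than for large lesions, and
exact recovery of configured FF in the noise-free limit. A separate
variance-component simulator (`simulate_measurement_table()`) generates
measurement tables directly from the one-way model with a known true ICC,
which is what validates the estimator itself (parameter recovery, CI
coverage, sample-size power) independently of any imaging.

## Numerical choices

* Percentiles interpolate linearly between closest ranks (`quantile`
  type 7); the convention matters for p10/p90 at small n and is stated
  because other dialects exist.
* Variance, skewness and kurtosis use population (n) normalisation;
  kurtosis is non-excess (Normal → 3). Samples smaller than 3 or with zero
  variance report skewness/kurtosis as missing, never as 0.
* Outlier removal is a single pass with the sample (n−1) SD; iterating to
  stability would be a different estimator.
* Order of preprocessing is fixed: resample → rescale → pool → trim.
* The resampling grid is anchored at the volume origin, so resampling onto
  the native spacing is the identity (this is what makes the noise-free
  phantom recover configured FF exactly on a 3 mm isotropic grid).
* Slice-area and connected-component ties are broken deterministically;
  every stochastic routine consumes a seed derived from one global seed via
  a label hash, so studies reproduce bit-for-bit.
* The Euclidean distance transform behind the reader model is an exact
  anisotropic Felzenszwalb transform in C++; a large finite sentinel is
  used for "no source" because infinities poison the lower-envelope
  arithmetic.

## Problem sizes

The default simulated study is 34 subjects (68 lesions, 204 segmentations);
one study takes a few seconds on a single core. The validation suite uses
500 replications at n = 500 for parameter recovery and CI coverage, 1000
replications for Levene size/power, 2000 for the sample-size power check,
and 20 independent studies for the ordering checks — sizes chosen to give
Monte-Carlo error comfortably below the tolerances being asserted.

## Known limitations

* Ellipsoidal lesions with a Gaussian interface are a deliberately simple
  geometry; infiltrative or confluent lesions, sclerotic components and
  treatment-related heterogeneity are not represented.
* The reader model captures boundary placement variability only — not
  lesion selection, not windowing, not fatigue or experience effects.
* Only first-order features are computed; texture matrices (and hence any
  2-D slice-wise texture convention) are out of scope.
* The statistics path assumes balanced cells (k identical repeats per
  subject); unbalanced tables are rejected rather than approximated.
* In-phase/out-of-phase Dixon channels are not modelled or used.
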