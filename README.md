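# ffrepro

Repeatability and reproducibility analysis for bone-marrow **fat-fraction
(FF%)** measurements from Dixon MRI.

Bone metastases replace fatty marrow with cellular tumor, lowering the local
fat fraction; FF% rises again as lesions respond to treatment. Before FF%
can be used to track response, its measurement error under manual lesion
segmentation must be quantified. `ffrepro` is aimed at quantitative-imaging
researchers who need that analysis as tested, reusable code: it implements
the full chain from Dixon volumes to agreement tables, plus a synthetic
phantom that makes every stage verifiable against known ground truth —
useful both for validating the statistics and for power/design exploration
of new reader studies.

## What it computes

* **FF% maps** — `FF% = 100·FO/(FO+WO)` from fat-only/water-only volumes,
  with explicit invalid-voxel handling and normalization of the two stored
  map dialects (×100 percent and ×1000 per-mille).
* **Lesion bookkeeping** — small (< 10 mm) vs large (≥ 10 mm) axial-diameter
  classification, largest-cross-section representative slice, single-slice
  vs volumetric masks, and the rule excluding single-slice lesions from
  volumetric measurement.
* **First-order features** — IBSI-consistent statistics (percentiles,
  median, RMS, variance, skewness, kurtosis, MAD/rMAD, energy, 64-bin
  entropy/uniformity) after the fixed preprocessing chain: resample to
  3×3×3 mm → rescale to percent → pool masked voxels → one-pass 3·SD
  outlier removal.
* **Agreement statistics** — one-way single-measure absolute-agreement
  ICC(1,1) with exact F-based confidence limits,

      ICC = (MS_B − MS_W) / (MS_B + (k−1)·MS_W),

  banded poor/moderate/good/excellent at 0.5/0.75/0.9; Bland–Altman bias
  and limits of agreement (bias ± 1.96·SD of differences); within-subject
  SD (√MS_W); Levene comparison of within-subject variances between size
  classes; bootstrap Spearman slice–volume correlation; and the
  Walter–Eliasziw–Donner reliability sample size

      n = 1 + 2k(z_α + z_β)² / ((k−1)·ln²C₀),  C₀ = (1+kθ₀)/(1+kθ₁),  θ = ρ/(1−ρ).

* **Synthetic study generator** — Dixon phantoms with ellipsoidal low-FF
  lesions in high-FF marrow, simulated readers that displace mask
  boundaries via a smooth random field on the signed distance function, and
  a direct variance-component simulator with known true ICC.

## Worked example

Simulate the default two-reader study (34 subjects, one small and one large
lesion each; reader 1 segments twice, reader 2 once) and analyse it:

```r
library(ffrepro)

walter_sample_size(rho0 = 0.75, rho1 = 0.9, k = 2, alpha = 0.05, power = 0.8)
#> [1] 33

res <- run_phantom_study(n_subjects = 34, seed = 1, n_boot = 500,
                         extract_features = FALSE)
print(res$report)
```

```
Agreement report

ICC (one-way single-measure absolute agreement):
 size_class   mode   comparison  n   icc   ci_low ci_high  category
      small  slice intra-reader 34 0.674  0.44177   0.822  moderate
      small  slice inter-reader 34 0.273 -0.06375   0.555      poor
      small volume intra-reader 23 0.690  0.40245   0.855  moderate
      small volume inter-reader 23 0.224 -0.19147   0.574      poor
      large  slice intra-reader 34 0.889  0.79042   0.943      good
      large  slice inter-reader 34 0.334  0.00388   0.600      poor
      large volume intra-reader 34 0.945  0.89384   0.972 excellent
      large volume inter-reader 34 0.433  0.11971   0.669      poor

Levene comparison of within-subject variances (small vs large):
   mode f_value df1 df2 p_value mean_score_small mean_score_large
  slice    1.96   1  66   0.166             2.31            1.098
 volume    2.05   1  55   0.158             1.53            0.761

Slice-volume Spearman correlation:
 size_class   n   rho ci_low ci_high
      small  69 0.769  0.597   0.886
      large 102 0.954  0.925   0.970
```

Reading the output: 33 is the minimum cohort for detecting an expected
reliability of 0.9 against a floor of 0.75 with two observations per
subject. In the simulated study, intra-reader ICC exceeds inter-reader ICC
in every cell (reader 2's systematic over-segmentation is charged to the
error term by the one-way model), agreement is higher for large lesions
than small ones in both measurement modes, and small lesions show larger
within-subject dispersion scores. ICC *magnitudes* depend on the simulated
reader noise and are not calibrated to any particular cohort — the
structural ordering is the reproducible finding (see the methods vignette,
`vignettes/ff-agreement-methods.Rmd`).

The statistics path runs equally on external data: put repeated
measurements in a CSV with columns
`subject_id, lesion_id, size_class, reader_id, repeat, mode, value` and call
`run_agreement_study(read_measurement_table("measurements.csv"))`.

A thin command-line wrapper with `simulate`, `ff`, `extract`, `agree` and
`pipeline` subcommands lives in `inst/cli/ffrepro.R`:

```sh
Rscript inst/cli/ffrepro.R pipeline --seed 1 --out out/
```

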