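# rtfrel

Reliability analysis of radiomic texture features (RTFs) from 2D parametric
maps — repeatability across segmentation runs, reproducibility across
scanner field strengths, and sensitivity to segmentation variability.

Radiomic texture features promise quantitative tissue characterization from
cardiac T1 maps, but two mundane pipeline variations threaten their use as
biomarkers: nobody draws the myocardial ROI the same way twice, and the same
heart imaged at 1.5 T and 3 T produces different intensity statistics.
`rtfrel` is for researchers who want to quantify both effects with standard
reliability statistics — and to test the whole machinery on synthetic
phantoms before touching clinical data.

## What it implements

* **Texture engine** — 93 features per image version: 18 first-order
  statistics plus the five gray-level matrix families (24 GLCM, 16 GLRLM,
  16 GLSZM, 14 GLDM, 5 NGTDM) from the standardized definitional formulas,
  computed in-plane (distance 1, four angles, 8-connectivity) after 1 mm
  resampling and fixed-bin-width discretization.
* **Filter bank** — eleven image versions: original; square, square root,
  logarithm, exponential (range-preserving point transforms); gradient
  magnitude; rotation-invariant uniform LBP (radius 1, 9 samples);
  single-level undecimated coiflet-1 wavelet sub-bands LL/LH/HL/HH.
  Total: 11 × 93 = 1023 named features per (map, mask).
* **Consensus overlap** — the three-mask IoU decomposition
  `IoU3 = |A1 ∩ A2 ∩ A3| / |A1 ∪ A2 ∪ A3|`, with `IoU2` the exactly-two
  fraction and `IoU1 = 1 − IoU2 − IoU3`, plus dataset averaging.
* **Reliability** — two-way ANOVA ICC estimation: ICC(2,1) (random effects,
  absolute agreement; repeatability), ICC(3,1) (mixed effects, consistency;
  reproducibility), and the k-averaged ICC(2,k)/ICC(3,k), each with F-based
  95% confidence intervals; four-tier categorization
  (excellent ≥ 0.95 > good ≥ 0.75 > moderate ≥ 0.5 > poor); global screening
  of degenerate (zero-variance) features; breakdowns by filter class and
  feature class.
* **Segmentation-variability model** — smooth random boundary displacement
  of a reference mask, calibrated so that three independent perturbations at
  the maximum level 0.3 agree at mean IoU3 ≈ 0.5, swept over the 16-level
  grid 0, 0.02, …, 0.30 with common random numbers.
* **Synthetic cohort** — annular T1-like phantoms (subject effects,
  Gaussian random-field texture, white noise) in paired field-strength
  versions sharing one texture realization, fully reproducible from a single
  master seed; optional NIfTI export.

## Worked example

```r
library(rtfrel)

spec <- phantom_spec(grid_shape = c(64, 64), ring_radii = c(10, 16))
cohort <- generate_cohort(
  cohort_config(n_subjects = 4, slices_per_subject = 2, master_seed = 7),
  spec)
cohort
#> rtf_cohort: 4 subjects x 2 slices x 2 fields (1p5T/3T) = 16 maps

## repeatability across three perturbed segmentation runs (level 0.1)
rep1 <- run_repeatability(cohort, level = 0.1)
rep1$iou
#> IoU3 = 0.7898  IoU2 = 0.0997  IoU1 = 0.1105
table(rep1$estimates$category)
#> excellent      good  moderate      poor
#>        80       185       219       488

## reproducibility across the two field strengths
repro <- run_reproducibility(cohort)
table(repro$estimates$category)
#> excellent      good  moderate      poor
#>       123       338       167       313
head(repro$breakdown_filter$top_features[
  order(-repro$breakdown_filter$top_features$icc), ], 3)
#>       group                     feature       icc     ci_lo     ci_hi
#>  squareroot  squareroot_glcm_SumEntropy 0.9981315 0.9907016 0.9996256
#>    original original_firstorder_Entropy 0.9979970 0.9900353 0.9995987
#>      square   square_firstorder_Entropy 0.9963340 0.9818217 0.9992650
```

The first block says that at perturbation level 0.1 about 79% of the pixels
in the union of the three masks are claimed by all three runs, and 80 of the
972 kept features still achieve excellent (ICC ≥ 0.95) repeatability on this
small demonstration cohort. The reproducibility block scores each feature's
consistency between the paired 1.5 T-like and 3 T-like maps and reports the
most consistent feature per filter class with its confidence interval.

At perturbation level 0 the three runs are identical and every kept feature
has ICC exactly 1 — a useful fixed point for validating the pipeline. The
full variability sweep is `run_dp_sweep(cohort)`; degenerate features (for
example the LBP first-order maximum, constant on every scan) are listed in
`rep1$screen$excluded`.

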