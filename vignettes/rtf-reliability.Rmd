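---
title: "Reliability of radiomic texture features from cardiac parametric maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of radiomic texture features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Radiomic texture features (RTFs) are quantitative descriptors of the spatial
arrangement of intensities inside a region of interest (ROI). On cardiac T1
parametric maps the ROI is the ring-shaped left-ventricular myocardium on a
short-axis slice, and two practical questions dominate any attempt to use
RTFs as imaging biomarkers:

1. **Repeatability** — if the same map is segmented several times (by a human
   a week apart, or by a stochastic neural segmenter), how much do the
   extracted features move?
2. **Reproducibility** — if the same subject is scanned at two field
   strengths (1.5 T vs 3 T), which features stay consistent despite the
   shifted intensity statistics?

`rtfrel` implements the full analysis chain for both questions: a texture
engine (93 features per image version, 11 versions, 1023 features per
map/mask pair), a three-mask consensus overlap decomposition, two-way ANOVA
intraclass correlation (ICC) estimation with F-based confidence intervals and
four-tier categorization, degenerate-feature screening, and a calibrated
segmentation-perturbation model swept over a 16-point variability grid.
Because no suitable public dataset of paired-field cardiac T1 maps exists,
the package also ships a synthetic phantom cohort generator so that every
stage is exercised end to end by code alone.

## The consensus IoU decomposition

Three masks $A_1, A_2, A_3$ of one map are compared by partitioning their
union into pixels claimed by exactly three, exactly two and exactly one
mask:

$$IoU_3 = \frac{|A_1 \cap A_2 \cap A_3|}{|A_1 \cup A_2 \cup A_3|},\qquad
  IoU_2 = \frac{|\{x \in \text{exactly two}\}|}{|A_1 \cup A_2 \cup A_3|},\qquad
  IoU_1 = 1 - IoU_3 - IoU_2.$$

The three components always sum to one, are invariant under permutation of
the masks, and $IoU_3$ can never exceed any pairwise IoU. We deliberately
define $IoU_2$ with the *exactly two* multiplicity: defining it from the
union of pairwise intersections would include the triple intersection and
double-count $IoU_3$, breaking the partition identity. Area is pixel count —
the pixel spacing cancels in every ratio — and there is no sub-pixel
treatment.

## The texture engine

### Preprocessing

Maps are resampled to 1 mm × 1 mm in-plane resolution (bilinear for the
image, nearest-neighbor for the mask) before anything else. Eleven image
versions are then built from the resampled full image, before ROI masking:

* **Point filters** (pixel-wise, range-preserving): square, square root,
  logarithm, exponential. With $m = \max|x|$ the transforms are
  $(x/\sqrt m)^2$, $\mathrm{sign}(x)\sqrt{m|x|}$,
  $\mathrm{sign}(x)\,\frac{m}{\log(1+m)}\log(1+|x|)$ and
  $e^{x \log(m)/m}$ — each maps the extreme magnitude back to itself, so the
  filtered intensity range matches the input range and one fixed gray-level
  bin width remains meaningful across versions.
* **Neighborhood filters**: gradient magnitude (central differences scaled
  by physical spacing), rotation-invariant uniform local binary patterns
  (radius 1, 9 circular samples, bilinear interpolation, codes in
  $[0, 10]$), and a single-level undecimated coiflet-1 wavelet decomposition
  (LL/LH/HL/HH, circular boundary, sub-bands kept at input size because the
  features are computed on the original ROI mask).

### Discretization

Gray levels are assigned by fixed-width binning anchored at the ROI minimum,
$\ell(x) = \lfloor (x - \min_{ROI})/w \rfloor + 1$, with default width
$w = 25$ map units. Fixed bin width (rather than a fixed bin count) is the
convention of the standard extraction tooling; it keeps the bin size
physically interpretable in T1 milliseconds. The width is exposed in
`extraction_settings()` because feature values — and the count of
surviving features on low-range filtered images — are sensitive to it. With
$w = 25$ the LBP image (range 0–10) collapses to a single gray level, so its
matrix-family features are constant and removed by screening; this is the
expected behavior of a fixed-width rule applied uniformly, not an error.

### Features

Per image version the engine computes 18 first-order statistics on the
original (undiscretized) ROI intensities — except entropy and uniformity,
which use the discretized histogram — and 75 matrix-family features:
24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM, all from the standardized
definitional formulas. Conventions that matter:

* 2D treatment throughout: distance-1 co-occurrence with the 4 unique
  in-plane offsets, 8-connectivity for zones and dependence, per-slice
  features. Angle-dependent families report the mean over per-angle feature
  values.
* GLDM dependence counts the center pixel plus qualifying neighbors
  ($|\Delta\ell| \le \alpha$, default $\alpha = 0$), so the matrix total
  equals the ROI pixel count.
* NGTDM includes pixels with no ROI neighbor with zero deviation, so a
  single-pixel ROI is valid.
* Degenerate fallbacks are explicit and documented where a formula is
  undefined: correlation-type GLCM features of a single-level matrix return
  1, entropy terms use $0 \log 0 = 0$, skewness/kurtosis of a constant ROI
  return 0, NGTDM coarseness of a zero-deviation ROI returns $10^6$.
  Screening, not silent numerics, is the mechanism that removes features
  degenerate across a whole cohort.

Every matrix builder and every feature formula is verified in the test suite
against an independent definition-literal implementation (explicit per-pixel
loops, flood fill with an explicit stack, literal double-sum formulas) on
dozens of random small ROIs at a relative tolerance of $10^{-9}$.

## Reliability estimation

Reliability is the fraction of measurement variance attributable to true
between-target differences. From the two-way crossed layout (targets ×
raters/conditions, no replication) with mean squares $MS_R$ (targets),
$MS_C$ (raters), $MS_E$ (residual):

* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement: used for repeatability across segmentation runs, where the
  run is a random draw from a population of segmenters.
* **ICC(3,1)** — two-way mixed effects, consistency: used for
  reproducibility across the two fixed field strengths. Consistency is
  invariant to a per-condition additive shift, but *not* to a multiplicative
  gain — a gain induces a target-by-condition interaction that lands in
  $MS_E$. The package's tests pin down both facts.
* **ICC(2,k), ICC(3,k)** — reliabilities of k-averaged measurements.

95% confidence intervals follow the standard F-based constructions for each
model (Satterthwaite degrees of freedom for the absolute-agreement models).
Point estimates are reported as computed, including negative values (which
categorize as poor); CI upper bounds are truncated at 1. Each estimate is
categorized as excellent ($\ge 0.95$), good ($\ge 0.75$), moderate
($\ge 0.5$) or poor ($< 0.5$), with inclusive lower boundaries.

Numerical edge policies: sums of squares below $10^{-12} \times SST$ are
snapped to zero, so identical raters yield ICC exactly 1 rather than
$1 - 10^{-16}$; an all-constant table is flagged degenerate and excluded
rather than scored; when near-perfect agreement pushes the Satterthwaite
degrees of freedom beyond $10^7$ the F quantile is taken at its
infinite-df limit.

Features that are constant across *all* observations (or non-finite
anywhere) are screened out globally before either analysis. On any cohort
generated here, `lbp-2D_firstorder_Maximum` is removed by this mechanism:
the rotation-invariant uniform LBP code range is $[0, P+1]$ and any textured
annulus attains the non-uniform code $P+1$ somewhere, so the per-ROI maximum
is the same constant for every scan.

The observational unit is the subject-slice (45 targets for the default
15-subject × 3-slice cohort), matching a design in which each slice is
segmented and extracted independently; slice nesting within subject is
ignored by the two-way models. The CI sample size is therefore $n = 45$.

## The synthetic cohort

The generator emulates the statistical structure the reliability analysis
assumes, with these defaults:

* **Geometry**: 96 × 96 grid at 1 mm, annulus radii 18/30 mm — a
  myocardium-like ring (~1800 pixels) without anatomical detail.
* **Intensities**: myocardial base 950 map units on a background plateau of
  100; between-subject effect $\sim N(0, 40^2)$ shared by a subject's
  slices; per-slice Gaussian random-field texture (sd 60, correlation length
  4 mm, smoothed-white-noise construction); white pixel noise sd 20. The
  values are free parameters chosen to resemble native T1 dispersion at
  1.5 T, not claims about any dataset.
* **Field pairing**: the second field shares the first's texture
  realization; its noise-free field is the affine image
  $1.25 x + 12.5$ (myocardial base ≈ 1200, qualitatively the higher signal
  level of a 3 T map) plus independent noise scaled by 1.2. Setting the
  shift to identity with shared noise reproduces the perfect-pairing limit.
* **Seeding**: one master seed; every map, subject effect and perturbation
  draws its own child seed through a counter-based polynomial hash, so any
  single object is regenerable in isolation and cohorts are bit-reproducible.

What the phantom does *not* model — and what passing tests therefore cannot
show about clinical data: partial-volume edges, motion and fitting artifacts
in T1 maps, anatomically realistic myocardial texture, B1/B0 field
inhomogeneity, or any disease effect. The cohort validates the *machinery*
(counts, invariants, anchors, monotone responses), not the magnitudes of
real-data reliability.

## Segmentation variability model

Stochastic segmentation runs are emulated by a boundary-displacement model:
the perturbed mask is the sub-level set $d(x) < \eta(x)$ of the signed
Euclidean distance $d$ to the reference boundary, where $\eta$ is a
standardized Gaussian random field (correlation length 6 mm) scaled to
`displacement_scale × level` millimeters. The largest 8-connected component
is kept. Level 0 returns the reference mask bit-for-bit, and the expected
pairwise overlap of two independent perturbations decreases in the level.

`displacement_scale = 9.5` mm per unit level was calibrated once, on the
default annulus, so that triplets at the maximum level 0.3 have mean
$IoU_3 \approx 0.5$ (measured 0.502 over 40 seed triplets; 7.5 gives 0.61,
8.5 gives 0.56). The constant is part of the model definition, not a per-run
tuning knob. Note the calibration is geometry-dependent: a smaller ring with
the same displacement scale yields a lower $IoU_3$ at the same level.

The sweep (`run_dp_sweep()`) evaluates the 16-level grid 0, 0.02, …, 0.30
with common random numbers: run seeds derive from (master seed, map, run)
but not from the level, so one displacement field per (map, run) is rescaled
across the grid. This makes the per-triplet overlap exactly monotone in the
level and removes almost all Monte Carlo noise from level-to-level
comparisons; the proportion of features per reliability category inherits a
near-monotone decline.

## Problem sizes

The shipped tests and the acceptance script use these sizes, chosen to keep
a full run comfortably on one CPU while preserving the designs they verify:
the zero-perturbation repeatability anchor runs the full 15 × 3 cohort
(45 targets, 3 runs, 135 extractions of 1023 features); the variability
sweep uses 5 subjects × 1 slice on the default geometry (240 extractions
across 16 levels); oracle equivalence uses 50 random 8 × 8 ROIs and 100
random balanced tables; parameter recovery uses 500 replicates of a
200 × 3 layout.

## Known limitations

* The feature engine targets numerical parity with its own definition-literal
  oracles, not bit-parity with any specific external tool release; tools
  differ in binning anchors, kurtosis offsets and LBP sampling conventions.
* Only the four-angle, distance-1, 2D configuration is implemented; no 3D
  features, no shape features, no Laplacian-of-Gaussian filter, and only
  single-level coiflet-1 wavelets.
* The consistency model treats the two scanners as fixed conditions; no
  generalization across scanner populations is implied.
* The perturbation model produces smooth boundary variation; it cannot
  emulate topological segmentation failures (missed wall segments,
  papillary-muscle inclusion) that a real segmenter occasionally produces.
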