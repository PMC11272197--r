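---
title: "Methods: abdominal adipose segmentation, volumetry and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abdominal adipose segmentation, volumetry and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposeg)
```

## The problem

On axial T1-weighted abdominal MRI, adipose tissue is hyperintense: the
subcutaneous fat (SAT) forms a bright ring between skin and abdominal wall,
and visceral fat (VAT) appears as bright regions among the darker organs and
muscle inside the abdominal cavity. Body-composition studies quantify both
compartments over a fixed block of slices — here 22 axial slices of 10 mm
acquired from the S1-L5 vertebral level upward, with slices 4 to 11 (eight
slices) used for quantification — and summarize visceral obesity as the
VAT/SAT volume ratio. Downstream, subject-level measures (BMI, HOMA-IR,
VAT/SAT ratio) are related to tabular outcomes such as regional cortical
thickness or PET SUVR with rank-based partial correlations under
false-discovery-rate control.

`adiposeg` implements this whole chain: a semi-automatic segmentation
pipeline, windowed volumetry, scripted manual editing, the statistical
procedures, and — because no subject data ship with the package — synthetic
phantoms and cohorts with known ground truth against which every stage is
validated.

## Segmentation pipeline

`voxa()` chains four per-slice stages. Every stage is strictly 2-D: the
acquisition is thick-slice (10 mm) 2-D gradient echo, and 3-D morphology
across 10 mm would couple unrelated anatomy.

### Intensity normalization (`normalize_stack()`)

Each slice is corrected for the scanner's multiplicative bias field and
contrast-stretched: the slice is divided by a heavily smoothed copy of
itself — modelled as the exponential of a low-order (default degree 2)
polynomial surface fitted to the log intensities of tissue voxels, with a
free per-class offset for the lean class so the surface follows the bias
rather than the fat/lean anatomy — and then rescaled so the 1st percentile
maps to 0 and the 99th to 1, clipping outside. Two numerical choices make
the operation well behaved:

* **Type-1 (inverse-ECDF) quantiles.** With interpolated quantiles the
  clipped stretch is not exactly reapplicable; with type-1 quantiles the
  stretch is a projection, so a stretched slice re-stretches to itself
  bit-for-bit.
* **Fixed-point iteration.** The flatten/stretch pair is iterated until the
  slice changes by less than `norm_tol` (default 1e-9, capped at
  `norm_maxit = 40` rounds). The returned image is therefore a fixed point,
  and renormalizing a normalized stack changes no voxel by more than the
  tolerance — the pipeline is safe against accidental double application.

A slice with no dynamic range (constant intensities, or a collapsed 1st-99th
percentile span) is refused with an error naming the slice. Division happens
on the linear scale, so exact zeros stay zero.

### Torso extraction (`extract_torso()`)

Air and tissue are separated per slice, by default with a hierarchical Otsu
rule: a T1 slice histogram is trimodal (air, lean, fat) and a single Otsu
threshold lands between fat and everything else, so a second Otsu below the
first isolates the air mode. The torso is then grown from the centroid of
the tissue bounding box along radial rays: every voxel is assigned to one of
`n_rays` (default 360) angular sectors and visited in order of increasing
radius; a ray stops at the first radial air gap of at least `ray_stop_run`
(default 3) voxel units. The union of ray extents is morphologically closed,
hole-filled and reduced to its largest connected component, so the returned
torso mask is simply connected.

Two robustness details: if the grown region captures less than half of the
tissue voxels (which happens exactly when the centroid sits on background,
e.g. a hollow slice), the method falls back to the largest connected tissue
component and records a warning in the stage log; and sector assignment
canonicalizes each direction into the first quadrant with exact quarter
turns before binning, which makes the whole pipeline exactly equivariant
under 90-degree grid rotations (a property the test suite asserts).

### Fat segmentation (`segment_fat()`)

Bright voxels inside the torso are adipose. The threshold defaults to Otsu
on torso-interior intensities (a clean lean/fat bimodal sample); a fixed
threshold is available for reproducing legacy analyses. Components smaller
than `min_component_vox` (default 5) voxels are discarded as speckle.
Raising a fixed threshold can only shrink the mask (monotonicity), and the
mask is always a subset of the torso.

### SAT/VAT separation (`split_sat_vat()`)

The subcutaneous ring and internal fat are split morphologically, per slice:

1. erode the fat mask with a disc of `erosion_radius_vox` (default 2) to
   break thin bridges between ring and internal fat;
2. label the connected components of the eroded mask;
3. components intersecting the band of width `boundary_band_vox` (default
   3) just inside the torso boundary become SAT seeds; all others VAT seeds;
4. seeds are restored to the full fat mask by geodesic reconstruction
   (dilation constrained to the fat mask);
5. fat voxels reachable from both classes — or from neither, such as
   components the erosion removed entirely — go to the class with the
   nearest seed under the Euclidean distance transform. Exact ties go to
   SAT: this is the conservative direction for the headline VAT/SAT ratio
   (it can only lower it), and it is configurable by swapping compartments
   in an edit script if a study prefers otherwise.
6. the non-VAT compartment is the dark (non-fat) tissue enclosed by the
   inner boundary of the SAT ring — cavity tissue, organs, muscle.

Steps 4-5 are implemented in an algebraically equivalent component-wise
form (a component whose seeds are all one class takes that class wholesale;
only mixed or seedless components pay for a distance transform), which
guarantees the partition contract exactly: SAT and VAT are disjoint and
their union is the input fat mask, for every input. If erosion erases a
slice's fat entirely, components are classified by direct boundary-band
contact; if nothing touches the band, the slice gets an empty SAT and a
logged warning rather than an error.

### Scripted manual editing (`apply_edits()`)

The "semi-automatic" step — an operator removing or adding misclassified
regions, canonically the spinal-region fat — is replaced by an ordered,
serializable `edit_script()` of add/remove/reassign operations on polygons
or masks. This keeps pipelines deterministic and auditable: the applied
script is recorded in the result and in the provenance sidecar written next
to the masks. Adds are clipped to the torso so the compartment invariants
survive editing; polygons must be simple and inside the grid, and violations
report the index of the offending edit.

## Volumetry

`compute_volumes()` counts voxels all-or-nothing (the masks are binary;
there is no partial-volume weighting) over an inclusive 1-based slice
window, default slices 4-11, and multiplies by the voxel volume
(row spacing x column spacing x slice thickness). The VAT/SAT ratio uses
window-restricted volumes for both numerator and denominator and is
undefined — flagged, not an error — when the SAT volume is zero. Volumes are
exactly additive over adjacent windows and scale linearly in slice
thickness.

## Cohort statistics

* `homa_ir()`: fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5,
  converting mg/dL glucose by 1/18.0182. Published unit strings for this
  index are often typographically inconsistent; the package standardizes on
  the uU/mL / mmol/L convention that the 22.5 divisor belongs to, and makes
  the unit an explicit argument rather than a guess.
* `bmi()` with the obesity predicate at BMI >= 30 kg/m2 (inclusive).
* `spearman_partial()`: all variables are rank-transformed (average ranks
  for ties) and the partial correlation is read off the inverse of the
  joint correlation matrix of the ranks. This is algebraically identical to
  residualizing the ranked variables on the ranked covariates and
  correlating residuals — the test suite verifies the equivalence to 1e-10
  against that brute-force oracle — and reduces exactly to ordinary
  Spearman with no covariates. The p-value uses the t approximation on
  n - 2 - k degrees of freedom; the exact permutation distribution is out
  of scope. Missing data are handled by listwise deletion per correlation
  (so different cells of a screen may have different n), and fewer than
  k + 4 complete rows are refused.
* `bh_adjust()`: Benjamini-Hochberg step-up control of the false discovery
  rate, with adjusted p-values and the rejected-iff-adjusted-p <= q
  equivalence. The implementation delegates the adjusted values to
  `stats::p.adjust(method = "BH")`; tests compare rejections and
  adjustments against an exhaustive O(m^2) transcription of the step-up
  definition.
* `correlation_screen()`: per predictor, partial Spearman against every
  outcome followed by BH within that predictor's family — the shape of a
  predictors-by-outcomes association table. The family size is whatever the
  outcomes list supplies; the multiplicity family for such tables is a
  study-design choice (published analyses sometimes state a family larger
  than the table they print), so the package takes the list as given.
  Stratified runs split on a column and drop it from the covariates.
  Whether to use rank-based partial correlation or an ordinary linear model
  is an explicit `method` switch, optionally accompanied by a reported
  Shapiro-Wilk statistic — never an automatic branch on the data, which
  would make results silently data-dependent.

## Synthetic data

### Phantoms (`generate_phantom()`)

The phantom is deliberately schematic: an elliptical torso (default 220 x
300 mm, tapering 5% across the stack) with a 25 mm SAT ring, a lean cavity
containing ellipsoidal VAT blobs kept at least 8 mm clear of the ring's
inner wall, organ-shaped lean exclusion zones, and a posterior spine
structure (lean vertebral body plus ~4 mm paraspinal fat pockets, the
classic target of manual spinal-fat removal). Intensities are three levels
(air 30, lean 300, fat 1000) composited into a label map; the ground-truth
masks are frozen from that label map before corruption, truth volumes are
exact voxel counts over the stated window, and the observed image then
receives a per-slice multiplicative second-order polynomial bias field
(default amplitude 0.15) and Rician noise (two Gaussian channels in
quadrature; sigma expressed as a fraction of the fat level, default 0.05).
The default in-plane grid is 128 x 128 at 3.5 mm — the in-plane matrix of
the emulated acquisition is not specified anywhere authoritative, so this
is a package choice balancing realism against test runtime, and it is fully
configurable. Default blob parameters put the windowed SAT volume around
1.5 L with VAT/SAT ratios around 0.2-0.3, within the range reported for
midlife cohorts.

What the phantom does *not* emulate: true anatomy (peritoneal boundaries,
bowel gas, partial-volume voxels), through-plane continuity of real organs,
k-space artefacts, or motion. Passing the phantom suite therefore shows the
pipeline recovers volumes and overlaps under controlled noise, bias and
geometry — not that it matches expert raters on clinical images.

A note on digitized volumes: a voxel-centre digitization of an ellipse
carries a lattice fluctuation of several voxels per slice regardless of
resolution, so analytic ellipse volumes and voxel-count truth volumes agree
only to a perimeter x spacing bound, and the truth volumes (exact counts)
are the reference the segmentation is scored against.

### Cohorts (`generate_cohort()`)

Tabular cohorts come from a Gaussian copula: a target Spearman matrix is
mapped to the copula's Pearson scale with the exact bivariate-normal
relation r = 2 sin(pi rho / 6), repaired to the nearest positive
semi-definite correlation matrix if necessary (`Matrix::nearPD`), sampled,
and pushed through rank-preserving marginal quantile functions (normal,
lognormal, gamma, uniform, binary). Binary sex is realized by thresholding
the copula normal, and an optional additive `sex_effect` shifts chosen
variables for males — used to emulate a higher VAT/SAT ratio in males.
Empirical Spearman matrices converge to the target (the suite checks a
planted rho of 0.55 to within 0.02 at n = 20000). All randomness descends
from the single seed in the spec; no function touches the global RNG state.

## Validation design and problem sizes

The test suite exercises the study conditions end to end: twenty seeded
phantoms at the default noise and bias (22 slices, segmented over the
8-slice analysis window) for volume and Dice recovery, plus noiseless
phantoms for the tighter overlap check; a 50-seed sweep for the partition
and containment invariants; 1000 null cohorts at n = 32 with 28 outcomes
for false-discovery control; 200 replicates at n = 21 (the PiB-subsample
size of the emulated design) for sign recovery of a planted rho = 0.55; and
200 replicates at n = 200 for detection of the planted pair within the
outcome family. The acceptance script (`scripts/acceptance.R`) recomputes
the same quantities from scratch at the same sizes, which keep the full run
within a few minutes on one CPU while leaving Monte-Carlo error well inside
the asserted margins. The segmentation tests run the analysis window rather
than all 22 slices because volumes and truth are window-restricted anyway;
whole-stack segmentation is exercised separately.

## Known limitations

* Single-peak assumptions: slices whose histogram is not approximately
  air/lean/fat trimodal (e.g. contrast-suppressed sequences) will
  mis-threshold; use fixed thresholds there.
* The SAT/VAT split relies on a lean gap or thin-bridge geometry between
  ring and internal fat; fat that genuinely fuses ring and viscera over a
  wide front is resolved by seed distance, which is only a heuristic —
  that is precisely the case the scripted editing exists for.
* The t approximation for the partial Spearman p-value is asymptotic; at
  very small n with heavy ties it is approximate.
* DICOM support is deliberately minimal (single-frame, explicit VR little
  endian, uncompressed) — enough to round-trip phantom series and enforce
  geometry metadata, not a general clinical reader.
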