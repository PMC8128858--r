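---
title: "Scoring focal and diffuse bone-marrow uptake in staging FDG-PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring focal and diffuse bone-marrow uptake in staging FDG-PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsau)
```

## The problem

At staging, FDG-PET/CT of a lymphoma patient shows bone-marrow uptake in
two patterns that must be read separately: *focal* lesions — discrete hot
spots in the skeleton that indicate marrow involvement and change the
stage — and *diffuse* uptake — a homogeneous elevation of the whole
marrow compartment, usually reactive/inflammatory rather than malignant.
Reader agreement on both calls is only moderate, which motivates an
objective, automated read-out. `tsau` implements that read-out given two
inputs on a common grid: an SUV volume and an integer label volume naming
each individual bone and the liver. Producing the segmentation is a
separate problem (solved upstream by a neural network in the system this
package models) and is deliberately out of scope; the grids must already
match exactly, because any resampling here would silently change every
downstream statistic.

## Bone-marrow definition

Marrow is obtained by eroding each bone by a class-specific physical
margin — 7 mm for humeri and femora, 5 mm for vertebrae and hip bones,
3 mm for everything else — so that cortical bone and edge voxels
(partial-volume mixtures of bone, muscle and fat) are excluded. Two
numerical choices matter:

* **Distances are Euclidean in mm**, computed with an exact separable
  distance transform that uses the per-axis voxel spacing. PET grids are
  often anisotropic; a voxel-count erosion would carve different shapes
  along different axes.
* **Erosion is per individual bone label**, so the boundary between two
  touching bones counts as an edge. Voxels exactly at the margin
  distance survive (the threshold is `>= margin`); the convention is
  arbitrary but fixed and documented.

A bone narrower than twice its margin simply contributes no marrow; that
is expected for ribs and clavicles at PET resolution and is not an
error.

## Spine and other-bones grouping

Diffuse uptake differs systematically between the axial and the
appendicular skeleton, so a single abnormality threshold would misfire.
Bones are therefore split into a *spine* group (vertebrae, sacrum,
coccyx) and an *other-bones* group, with one refinement: hip-bone voxels
within 50 mm of any vertebra/sacrum/coccyx voxel are counted as spine,
which captures the sacroiliac joints. The reference set for that 50 mm
rule is the nearest labelled voxel (surface distance), the simplest
reading consistent with a voxelwise pipeline; the distance is inclusive
(`<= 50` mm). An empty spine group is an error, because every downstream
statistic is undefined without it.

## The focal detector

For each group the threshold is

$$\mathrm{THR} = \mathrm{SUV}_{mean} + 2\,\mathrm{SD}$$

over that group's marrow voxels. The SD is the population SD (divide by
N); with thousands of marrow voxels the difference from the sample SD is
negligible, but fixing it makes results bit-reproducible. The threshold
is computed in a single pass: no iterative exclusion of suprathreshold
voxels is attempted, so a large lesion inside the marrow inflates THR
somewhat. That is a property of the method being modelled, and the tests
account for it.

The *abnormal bone region* is then built in three ordered steps:

1. **Candidates** — bone voxels of the group with SUV strictly above
   THR.
2. **Spill-over removal** — a watershed transform of the negated SUV
   image, computed over the whole volume, assigns every voxel to the
   catchment basin of a regional SUV maximum. Candidates whose basin
   maximum lies outside the *full* skeletal mask (both groups — a peak
   in another bone is not soft-tissue spill-over) are removed: their
   uptake is leaking into bone from an adjacent hot structure through
   the scanner point-spread function. The watershed uses steepest-ascent
   flooding in decreasing-SUV order; plateaus are merged into a single
   maximum and all ties break by lexicographic voxel order, so the
   decomposition is deterministic.
3. **Size filter** — 26-connected components smaller than 0.1 mL are
   removed (strictly smaller: a region of exactly 0.1 mL survives).
   Components, not watershed basins, are the unit here: after basin-based
   removal the surviving voxel set is the natural object to filter, and
   the filter is idempotent.

The group's score pools all surviving voxels into one region:

$$\mathrm{MSAU} = \frac{1}{|R|}\sum_{v \in R}(\mathrm{SUV}_v-\mathrm{THR})^2,
\qquad \mathrm{TSAU} = \mathrm{MSAU}\times\mathrm{vol}(R)$$

with MSAU of an empty region defined as 0 so that TSAU is 0 without
special-casing. TSAU equals the voxel-volume-weighted sum of squared
excess, an identity the acceptance script verifies to machine precision.
The case is *focal* when spine TSAU > 0.5 or other TSAU > 3.0; the
inequalities are strict, matching "higher than" in the clinical rule.

`tune_cutoff()` reproduces the calibration of those cut-offs on scored
training cases: candidate cut-offs at midpoints between consecutive
unique scores, a positive-predictive-value target of 65% under a
negative-predictive-value floor of 98%. Both targets read as floors:
among NPV-eligible candidates those reaching the PPV target are
preferred (taking the most specific, i.e. highest-PPV, one); only when
no candidate reaches the target is the closest PPV returned. On
perfectly separable data this lands in the separating gap.

## The diffuse index

The index is the median SUV over the vertebral marrow divided by the
median SUV over the liver, with high diffuse uptake called strictly
above 1.0. The median (not the maximum) keeps the index robust to focal
lesions; the index is invariant under global rescaling of the SUV
volume. Two choices are deliberately conservative:

* The numerator uses the marrow of the vertebrae, sacrum and coccyx
  only — hip-bone voxels attributed to the spine *group* by the 50 mm
  rule are excluded, because the index is a vertebral-marrow statistic.
* The liver median is taken after a 5 mm erosion (configurable via
  `liver_margin_mm`) to exclude edge voxels; the exact margin used by
  the automated reference system is not published, and reported liver
  volumes (hundreds to thousands of mL) imply little erosion, so the
  default mirrors the mid-size bone margin and falls back to the full
  label if erosion would empty the liver.

`manual_roi_index()` runs the identical computation over small
caller-supplied spherical or box ROIs, emulating the manual
quality-control procedure (a 1–3 cm³ ROI in the L3/L4 marrow, a small
ROI in the upper right liver). When marrow and liver are homogeneous the
two paths agree exactly; a focal lesion at the manual ROI site drives
the manual index above the automated whole-spine one — the outlier
mechanism seen when the two methods are compared with `bland_altman()`
(mean difference and mean ± 1.96 SD limits of agreement).

## Reader agreement

Readers classify each case into four categories (1 low-diffuse/no-focal,
2 low/focal, 3 high/no-focal, 4 high/focal). Each analysis dichotomizes
one view: focal = {2,4}, diffuse = {3,4}. Agreement between two readers
is summarized by percentage agreement and Cohen's kappa
$\kappa = (P_o-P_e)/(1-P_e)$; for a panel, all $\binom{n}{2}$ pairs are
tabulated with mean and range. Kappa is the two-rater Cohen form
throughout — panel results are reported pairwise, not with a multi-rater
coefficient. When both raters are constant and identical, $P_e = 1$ and
kappa is undefined; it is reported as missing (never coerced to 0 or 1)
and excluded from means with an explicit count. Display rounding is
half-up to 2 decimals, and the verbal bands (slight/fair/moderate/
substantial/almost perfect) apply to the rounded value with closed
boundaries. Majority votes are strict; an exact split is reported as a
tie and kept separate when comparing the panel consensus with the
automated verdicts.

## The phantom

The generator emulates the statistical structure the detector assumes,
not anatomy: a labelled geometric skeleton (a stack of vertebral
cylinders, sacrum/coccyx, hip spheres straddling the 50 mm shell at the
default lateral offset, femoral/humeral tubes, rib arcs, scapulae,
clavicles, sternum) and a liver ellipsoid on a PET-like 3 mm isotropic
grid (96 × 96 × 192 voxels by default; geometry scales with the grid
extent). Uptake regimes: marrow $\mathcal N(1.5, 0.2)$ clipped at 0
inside a 2 mm cortical shell held at SUV 1.0, liver
$\mathcal N(2.0, 0.2)$, soft tissue 0.7 with SD 0.1 — typical values for
an untreated staging examination, giving a default diffuse index of
0.75 (low). Lesions are stamped as spherical plateaus, then the whole
volume is convolved with a Gaussian point-spread function (6 mm FWHM by
default, a typical clinical reconstruction). The PSF belongs to the
phantom, not the detector: spill-over from hot nodes adjacent to bone is
*created* by the blur exactly as the scanner creates it, and the
detector is tested on blurred data.

The truth manifest records, per lesion, the stamped volume and the
post-blur suprathreshold volumes (overall and within bone) at the
analytic threshold $\mu + 2\sigma = 1.9$, the per-group truth TSAU, the
expected focal verdict under the default cut-offs, and the true diffuse
index $\mu_{marrow}/\mu_{liver}$. A fixed seed fixes the volume
bit-for-bit, and generation never disturbs the caller's RNG stream.

What the phantom does *not* model: anatomical shape variation, CT-based
attenuation artefacts, non-Gaussian scanner noise, respiratory motion,
PET/CT misalignment, and physiological confounders (brown fat,
degenerative uptake) that human readers discount. Passing the phantom
battery therefore demonstrates the correctness of the pipeline's
mechanics — mm-exact erosion, basin attribution, volume accounting,
threshold statistics — not clinical performance on patients.

## Problem sizes and numerical choices

Unit and acceptance tests run the multi-seed properties on a compact
phantom (64 × 64 × 96 voxels at 3 mm, the same 3 mm grid and uptake
regimes as the default) so the full battery of dozens of phantoms stays
fast; single end-to-end checks use the full default grid. Specific
settings per property:

* **Threshold recovery** (20 seeds, |THR − 1.9| < 0.05) runs with the
  PSF off: the property checks the sampling distribution of the marrow
  statistics, and smoothing would deliberately shrink the SD toward a
  different (blur-dependent) target.
* **Spill-over discrimination** (20 seeds, ≥ 19 must succeed) uses the
  default 6 mm blur, one lesion inside a vertebra (radius 6 mm, peak 12)
  and one node touching the spine surface (radius 6 mm, peak 25); the
  test also verifies the node actually lights up candidate bone voxels,
  so the property is never vacuously true.
* **Size filter** uses the PSF off so that stamped lesion volumes
  (~0.03 mL vs ~0.19 mL) are exactly what the filter sees; with blur on,
  the suprathreshold footprint of even a sub-voxel lesion can exceed
  0.1 mL, which is a property of resolution, not of the filter.
* Erosion thresholds (`>= margin`), the inclusive 50 mm rule, strict
  SUV > THR and strict TSAU/index cut-offs, lexicographic watershed
  tie-breaks, and midpoint medians for even counts are all fixed
  conventions chosen once where the clinical description is silent.

## Known limitations

* The detector inherits the single-pass THR: very large lesions raise
  their own threshold and shrink their measured abnormal volume.
* The watershed operates on the raw (blurred) SUV landscape; noise
  maxima inside bone can keep a few spill-over voxels, which the 0.1 mL
  filter then usually removes. The multi-seed acceptance property
  allows one failure in twenty for this reason.
* Whether the automated vertebral median should include the sacrum and
  coccyx is ambiguous in the clinical description; this implementation
  includes them (they are axial marrow) and exposes the masks so the
  alternative is one intersection away.
* No partial-volume correction is attempted anywhere; margins and the
  liver erosion are the only defence against edge mixtures.
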