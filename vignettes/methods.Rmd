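---
title: "Methods: reference-normalized PET volume delineation and MRI concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-normalized PET volume delineation and MRI concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`petconcord` at the level of detail a user needs to judge what the package
computes and what its tests do and do not establish.

## Coordinate and grid conventions

All volumes are `volume_image` objects: a 3D array plus a positive voxel
spacing (mm per axis) and the world position of the first voxel's *center*.
Array axes (i, j, k) map to world axes (x, y, z) in a right-handed frame;
voxel `[i, j, k]` (1-based) is centered at `origin + (c(i,j,k) - 1) *
spacing`. NIfTI-1 files are written with this geometry in both sform and
qform; reading is restricted to axis-aligned volumes with positive
diagonal xforms, which is what every file produced by the package
satisfies. On disk, intensities are 32-bit float (round-trip error bounded
by `max|v| * 2^-23`) and masks are 8-bit unsigned holding exactly 0/1.

## SUV normalization

`compute_suv()` maps an activity-concentration volume (kBq/mL) to
standardized uptake values: `SUV = concentration / (injected activity per
gram of body weight)`, so a concentration numerically equal to the injected
dose per gram gives SUV = 1. Decay correction is a scalar applied to the
injected activity *upstream* of this call: the pipeline targets a single
static acquisition at a fixed post-injection time, for which a voxelwise
decay factor adds nothing. SUV maps carry their normalization provenance
(dose, weight) with them.

`interpolate_halve()` mirrors the console-style interpolation step applied
to PET images: output spacing is halved on every axis and voxel counts are
exactly doubled, cell-centered, so the physical extent of the image is
preserved. The kernel is separable linear interpolation — monotone, exact
for constants, and never producing values outside the input range. The two
outermost fine voxels per axis sit a quarter-voxel outside the coarse
center range and replicate the edge value (clamping); consequently an
interior extremum of the coarse image is approached but not necessarily
attained on the fine grid, which is the price of the exactly-2x
cell-centered output shape. The original console software's kernel is not
documented anywhere we could rely on; trilinear is a stand-in chosen for
being standard and monotone, not a claim about the scanner.

`resample_to()` pulls a moving volume onto a reference grid through an
affine mapping moving world coordinates into the reference frame
(registration itself is out of scope; phantoms use the identity).
Intensities use trilinear interpolation, masks nearest-neighbor (so masks
stay strictly 0/1), and anything mapping outside the moving image is 0.

## The three ROIs

**Reference spheres.** The tumor center is mirrored across the midline
plane (default: the sagittal plane x = 0, which is exact for the centered
phantom grids). Three spheres of radius 5 mm are placed at the mirrored
point and at ±2 radii along the superior-inferior axis, falling back to ±4
and ±6 radii when a position would leave the grid or cross the midline;
fewer than three valid positions is an error. N~max~ and N~mean~ are
pooled over the *union* of the three spheres, treating "normal brain" as
one statistic. Sphere radius, offsets and the pooling rule are package
decisions — reproducible stand-ins for what is done manually in clinical
practice — and all three are configurable through `segmentation_config()`.

**Contrast-enhancement ROI.** Clinical delineation of the enhanced volume
is semiautomatic and operator-dependent; the package uses the simplest
reproducible proxy: threshold at `mean + mri_k * sd` (default k = 3) of
the T1 intensities inside a normal-tissue mask (the reference spheres),
keep the connected component containing a user seed, and fill enclosed
cavities. The seed must itself exceed the threshold, otherwise the call
errors rather than guessing.

**Metabolic ROI.** Voxels with `SUV > 3.0 * Nmax` — strict inequality,
reading the conventional "> 3.0" criterion literally — form the candidate
set. Exclusion masks (physiological uptake: venous sinus, choroid plexus)
are inputs, not derived from anatomy; they are removed before component
selection *and again after cavity filling*, so the output never intersects
an exclusion even when one sits inside the tumor. Continuity cleaning
(seeded component + cavity fill) automates the manual edit of removing
discontinuous areas and filling the inside of the core; `clean_mask()` is
idempotent.

Connected components use 26-connectivity for foreground and 6-connectivity
for the background flood in cavity filling — the standard complementary
pair that avoids topological paradoxes. Both operations are implemented in
C++ (breadth-first search); cavity filling runs on the foreground bounding
box plus a one-voxel pad, which is equivalent to the full-grid computation
and independent of image size.

## Concordance and margin metrics

Overlap Volume `|A∩B| / min(|A|,|B|)` and DICE `2|A∩B| / (|A|+|B|)` are
computed on voxel *counts* of the shared (T1-resolution) grid, making both
formulas exact integer arithmetic; volumes in mL are `count * voxel volume
/ 1000`. DICE never exceeds the overlap volume, and overlap volume is 1
exactly when one mask contains the other. The margin region is the set
difference ROI~FBY~ \ ROI~MRI~; when it is empty, its SUV~mean~ is
reported as `NA` with `margin_defined = FALSE` — never as 0, which would
corrupt group means. The lesion SUV~max~ is taken over the union of the
two ROIs, and the T/N ratio is SUV~max~/N~max~. Whether concordance should
be evaluated on the PET or the MRI grid is unstated in clinical practice;
the package fixes the T1 grid (the resampling target) and documents that
choice here.

## Cohort statistics

The clinical literature names the tests but rarely the variants; the
package fixes safe defaults for small unbalanced groups (16 vs 7):

* **Welch** (unequal-variance) t-test, two-sided, for age, SUV metrics,
  reference values and volumes;
* **Wilcoxon rank-sum**, two-sided, for the concordance scores and margin
  statistics: exact enumeration when the combined n is at most 25 and
  tie-free, otherwise the tie-corrected, continuity-corrected normal
  approximation;
* **Wilcoxon signed-rank** for the paired SUV~mean~ comparison under the
  two ROIs, dropping zero differences (Wilcoxon's original treatment);
  up to 16 nonzero differences all 2^n sign patterns are enumerated
  directly, which keeps the test exact even with tied absolute
  differences, 17–25 tie-free differences use the exact signed-rank
  distribution, anything else the corrected normal approximation;
* **Fisher's exact test** for the 2×2 sex table.

No multiple-testing correction is applied, matching the descriptive-table
setting the pipeline reproduces. Degenerate variables (e.g. a metric that
is constant in both groups on noise-free phantoms) are summarized with an
undefined test rather than failing the whole table; an all-zero paired
difference, by contrast, is surfaced as an error because it indicates the
two ROIs are identical everywhere. The underlying numerics are
`stats::wilcox.test`, `stats::t.test` and `stats::fisher.test` (plus the
package's own small-sample sign-pattern enumeration); the test suite
cross-checks them against independent brute-force enumerations.

## The phantom generator

`phantom_spec()` defines the synthetic study conditions; the defaults were
fixed once, from the imaging characteristics the pipeline targets, and are
not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| grid | 96³ @ 1.5 mm iso | PET-like field of view at interpolated resolution; midline exactly x = 0 |
| brain radius | 60 mm | adult hemispheric scale, fits the grid with margin |
| tumor center / core radius | (25, 5, 0) mm / 10 mm | off-midline lesion, ~4 mL core |
| core SUV | 2.5 | typical amino-acid-PET tumor uptake |
| background SUV | N(0.037, 0.022) truncated at 0 | mean matches low-background amino-acid tracers; sd set so the max over the ~465 reference-sphere voxels (≈ 3.5 sd above the mean, by the expected maximum of that many Gaussians) lands near 0.116 |
| margin SUV | taper 1.0 → 0.45 | linear decrease with distance emulates an infiltration front; the floor keeps the whole shell above 3×N~max~ with headroom, and the resulting margin SUV~mean~ sits in the 0.6–0.7 range |
| MRI | background 100 ± 5, core +100 | enhancement ≈ 20 noise sd: unambiguous but not noise-free |
| cohort | 16 diffuse (margin U(3,9) mm) vs 7 circumscribed (U(0,1) mm) | the two-group design and sizes of the target study |

Seed policy: one master seed; per-phantom seeds are `master + patient
index`; widths and demographics are drawn under the master seed, so the
whole cohort is bit-reproducible. PET activity files written by
`run_simulate()` are derived by inverting the SUV normalization with the
patient's dose and weight, so the file-reading pipeline genuinely
exercises `compute_suv()`.

**What the phantoms do not emulate:** anatomy (the brain is a sphere; no
gray/white contrast, no ventricles), PET physics (no point-spread blurring,
no reconstruction artifacts, no partial-volume effect at the tumor rim),
spatially correlated noise, registration error (volumes are generated
aligned), or biological heterogeneity of uptake inside the core. Passing
tests therefore demonstrate that the *pipeline* — thresholds, components,
set arithmetic, statistics — is correct and recovers a known geometry
under i.i.d. Gaussian noise; they do not validate clinical performance on
real images, where resolution mismatch and partial-volume effects are the
dominant error sources.

## Problem sizes and runtime choices

The test suite exercises compact 48³ phantoms for unit-level checks and
the full 96³ defaults for the end-to-end properties: ground-truth recovery
on 20 noisy phantoms, the containment property on the 23-patient default
cohort, and the diffuse-vs-circumscribed rank-sum rejection rate over 100
replicate cohorts. The acceptance script repeats the default cohort
analysis and the 100-replicate rejection rate from a user-supplied seed.
These sizes keep a complete run in the minutes range on a single CPU while
leaving the group contrast overwhelmingly detectable (the two margin-width
ranges do not overlap, so the truth-level DICE distributions separate
completely).

## Known limitations

* Only axis-aligned NIfTI volumes are supported; oblique acquisitions must
  be reoriented upstream.
* The ROI~MRI~ rule is a threshold proxy; real contrast enhancement is
  heterogeneous and clinical delineation may differ systematically.
* Reference-sphere placement assumes the contralateral hemisphere is
  normal; bilateral disease would violate it.
* The signed-rank enumeration bound (2^16 patterns) is generous for the
  cohort sizes targeted here but quadratic growth makes it unsuitable for
  hundreds of pairs; those fall back to the normal approximation.
* The clinical cohort behind the study design is not publicly available,
  so the package's quantitative outputs on phantoms are qualitative twins
  of the published relationships, not reproductions of the printed values.
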