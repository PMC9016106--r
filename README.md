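# petconcord

Volumetric concordance of PET metabolic and MRI contrast-enhanced brain
tumor volumes.

## The problem

For contrast-enhancing brain tumors, the surgical target is conventionally
the contrast-enhanced volume on T1-weighted MRI. Amino-acid PET tracers,
however, often show metabolic activity *beyond* the enhancing rim —
particularly in diffuse gliomas, which infiltrate the surrounding
parenchyma — and that margin matters for resection planning, radiotherapy
and boron neutron capture therapy. `petconcord` implements the full
quantitative pipeline for asking "how much metabolic tumor lies outside
contrast enhancement, and does that differ between diffuse and
circumscribed tumors?":

1. **SUV normalization** — an activity-concentration volume (kBq/mL) is
   converted to standardized uptake values,
   `SUV = activity / (injected activity / body weight)`, with the injected
   activity decay-corrected to scan time.
2. **Reference region** — three spheres mirrored onto the contralateral
   normal cortex give the normal-brain maximum and mean SUV
   (N<sub>max</sub>, N<sub>mean</sub>).
3. **Three ROIs** — ROI<sub>REF</sub> (the spheres), ROI<sub>MRI</sub>
   (contrast-enhanced volume, thresholded at mean + 3 sd of normal-tissue
   intensity and grown from a seed), and ROI<sub>FBY</sub> (metabolic
   volume: voxels with SUV / N<sub>max</sub> > 3.0, cleaned for spatial
   continuity, physiological uptake such as the venous sinus removed).
4. **Concordance scores** on the shared voxel grid:

   - Overlap Volume = |V<sub>MRI</sub> ∩ V<sub>FBY</sub>| / min(|V<sub>MRI</sub>|, |V<sub>FBY</sub>|)
   - DICE = 2 |V<sub>MRI</sub> ∩ V<sub>FBY</sub>| / (|V<sub>MRI</sub>| + |V<sub>FBY</sub>|)

   plus SUV<sub>max</sub>, the tumor-to-normal ratio
   SUV<sub>max</sub>/N<sub>max</sub>, SUV<sub>mean</sub> under each ROI,
   and the uptake statistics of the **margin region**
   ROI<sub>FBY</sub> \ ROI<sub>MRI</sub>.
5. **Cohort statistics** — mean ± sd summaries with Welch t-tests, Wilcoxon
   rank-sum tests (concordance scores, margin statistics), Wilcoxon
   signed-rank tests (paired SUV<sub>mean</sub> under the two ROIs) and
   Fisher's exact test (sex distribution).

Because clinical paired PET/MRI datasets of this kind are not publicly
deposited, the package ships a **digital phantom generator**: paired
T1-like and SUV volumes containing a spherical brain with low background
uptake, an enhancing tumor core, an optional infiltration shell whose
uptake tapers off with distance (diffuse geometry), and an optional hot
physiological structure. Every phantom carries voxel-level ground truth, so
segmentation accuracy, the concordance formulas and the group contrast are
all testable end to end.

## Worked example

```r
library(petconcord)

# one diffuse phantom: 10 mm enhancing core + 6 mm infiltration margin
ph  <- generate_phantom(phantom_spec(margin_width = 6, seed = 42))
res <- analyze_phantom(ph, verbose = TRUE)
#>   MRI threshold 114.9; FBY threshold 0.2875 (3.0 x Nmax 0.09584)
res$stats
#> <reference_stats> Nmax = 0.0958, Nmean = 0.0358 (3 spheres, r = 5.0 mm)
res$metrics[, c("volume_mri", "volume_fby", "overlap_volume", "dice",
                "suv_max", "tn_ratio", "suv_mean_margin", "margin_over_nmax")]
#>   volume_mri volume_fby overlap_volume  dice suv_max tn_ratio suv_mean_margin
#> 1       4.22       17.2              1 0.393     2.5     26.1           0.681
#>   margin_over_nmax
#> 1             7.11
```

The enhancing volume (4.2 mL) is entirely contained in the metabolic volume
(17.2 mL): overlap volume 1, DICE 0.39. The margin's mean SUV (0.68) is 7.1
times N<sub>max</sub> — comfortably above the 3.0 threshold used for
biologic target delineation.

A full two-group synthetic cohort (16 diffuse, 7 circumscribed patients):

```r
cohort  <- generate_cohort(seed = 7)
records <- analyze_cohort(cohort)
tabs    <- build_cohort_tables(records)
glance(tabs)
#>   group1  group2        n_group1 n_group2 dice_group1 dice_group2     dice_p
#> 1 diffuse circumscribed       16        7       0.452       0.923 0.00000816
#>   overlap_group1 overlap_group2 overlap_p
#> 1              1          0.999  0.000253
```

Diffuse phantoms show much lower DICE than circumscribed ones (0.45 vs
0.92, rank-sum p ≈ 8e-6) while the overlap volume stays ≈ 1 in both groups
— the diffuse metabolic volume grows *around* the enhancing core rather
than away from it. `tidy(tabs)` returns every comparison as a tibble;
`autoplot(tabs)` and `plot_volume_comparison(records)` draw the standard
displays.

The file-based pipeline (`run_simulate()`, `run_patient()`,
`run_cohort()`) exchanges NIfTI-1 volumes plus JSON sidecars and writes
per-patient metrics CSV/JSON, the cohort table and a test report; the
`exec/petconcord` script exposes the same steps as shell subcommands.

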