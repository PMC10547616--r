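---
title: "Methods: automated bone-marrow burden quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated bone-marrow burden quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `marrowmtv`, the
conventions that pin down every numerically ambiguous step, the design of
the synthetic generators, and what the test suite does and does not
establish.

## The quantification model

The pipeline estimates the metabolically active myeloma burden of the
skeleton from a body-weight SUV PET volume and a co-registered integer
label map of 17 bones, the liver and the gluteus maximus. Three steps:

1. **Reference statistics.** Liver SUV median and maximum and gluteus
   SUV median over the *entire* organ masks. Medians are used for the
   relative thresholds because they are insensitive to a small fraction of
   mislabeled or misaligned voxels; the liver maximum serves the most
   conservative approach. Spherical sub-VOIs (common in manual reading)
   are deliberately not used: the automated method has whole-organ masks
   available, and a fixed sub-volume would re-introduce placement
   subjectivity.

2. **Group-wise thresholding.** Skeletal labels are partitioned into the
   axial skeleton and the extremities, which carry different physiological
   marrow uptake. Each approach resolves to two numbers `(t_axial,
   t_extremity)`; a voxel is segmented iff its group threshold is met with
   an *inclusive* comparison (SUV ≥ t). Reference organs, background and
   EXCLUDED labels (skull) are never segmented. The skull exclusion is a
   fixed methodological rule — the brain's intense physiological FDG
   uptake spills into the calvarium and would dominate any threshold.

3. **Spill-over refinement.** PET's limited spatial resolution lets
   adjacent hot tissue bleed into the bone mask. The mask is therefore
   partitioned into watershed basins of local SUV maxima (Meyer's
   flooding restricted to the mask), and basins — 18-connected components
   within one basin label — with physical volume strictly below 1 mL are
   discarded. Exactly 1.0 mL survives ("less than 1 mL" is removed).
   Volumes use the physical voxel volume from the NIfTI spacing, so
   anisotropic grids are handled correctly.

MTV is the voxel count of the refined mask times the voxel volume (mL);
TLG is `SUVmean × MTV` over the same voxels, numerically identical to
`Σ SUV × voxel_volume / 1000` (asserted to 1e-9 relative tolerance in the
suite), and reported in grams by the SUV-as-g/mL convention. An empty
refined mask is a legal outcome with MTV = TLG = 0, not an error: the
strictest approach frequently segments nothing in low-burden patients.

## Determinism of the watershed

Meyer's flooding leaves plateau handling and tie-breaking open; testability
requires fixing both. `marrowmtv` uses the strict total order
`key(v) = (−SUV, z, y, x)` and these rules:

- **Regional maxima.** Connected plateaus (equal SUV, in-mask adjacency)
  with no strictly greater in-mask neighbor anywhere seed one region each,
  at the lexicographically smallest member. Equal-height maxima joined by
  a plateau therefore merge into a single region rather than producing an
  arbitrary split.
- **Strict ascent.** A voxel with at least one strictly greater in-mask
  neighbor is claimed by its highest-SUV strictly greater neighbor,
  lexicographic tie-break — the descending-SUV claim order of a priority
  flood.
- **Draining plateaus.** A plateau that is not a regional maximum routes
  every member without a strictly greater neighbor through the plateau's
  lexicographically smallest *exit* (member that does have one).

Every mask voxel is assigned (no watershed-line voxels), flooding never
crosses the mask boundary, and each region is 18-connected by
construction. The same 18-neighborhood (faces + edges, not corners) is
used for flooding and component filtering, so the partition and the
component analysis cannot disagree; 6 and 26 are available behind the
`connectivity` argument. An independent steepest-ascent oracle implementing
the same three rules by per-voxel hill climbing reproduces the labeling on
randomized tied fields — that equivalence is an acceptance criterion, and
it is what makes "deterministic" checkable rather than asserted.

Components are computed per watershed label (the documented reading of the
postprocessing); computing them on the union mask instead is available via
`per_label = FALSE`.

## Geometry conventions

Voxel indices are 0-based in all reports. Label maps whose grid differs
from the PET are transferred by nearest-neighbor lookup through the two
NIfTI affines (sform when present, else a diagonal pixdim affine): labels
are categorical and interpolation would invent anatomy. The transfer is
idempotent on identical geometry and can only shrink the label set. How
the original clinical software resampled CT-space labels is not documented
anywhere we could rely on; nearest-neighbor through header affines is our
declared assumption.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_volume_ml` | 1.0 | mL | published component cutoff; inclusive keep |
| `connectivity` | 18 | — | stated component connectivity; one neighborhood throughout |
| approach multipliers | ×1.1/×1.5/×2 (liver), ×4 (gluteus) | — | the six published approaches, encoded declaratively |
| absolute thresholds | 2.5 / 2.0 | SUV | published absolute approaches |
| `moderate_factor`, `intense_factor` | 1.1, 2 | × liver | visual-grade bins |

The grade bins as printed leave `(1.0, 1.1] × liver` unassigned; this
implementation grades that gap `negative_mild` (the conservative reading),
declared rather than inferred, and configurable.

## The synthetic generators

**Phantom** (`phantom_spec()` / `generate_phantom()`). A crude whole-body
layout — boxes, cylinders, ellipsoids and slabs carrying the full 17-bone
label vocabulary plus liver, gluteus and an optional hot EXCLUDED skull —
on a 96×96×192 grid at 4 mm isotropic spacing by default (whole-body PET
resolution at desk-scale runtime). Default uptakes: liver 2.0, gluteus
0.5, diffuse marrow 1.2 axial / 0.7 appendicular, soft tissue 0.4 — chosen
once so that all six approaches resolve to thresholds above the diffuse
level and all three visual grades are reachable. Four default focal
lesions (10 mm radius, peaks 4–7, ≈4 mL each) sit in vertebrae, pelvis and
femur, mutually separated by more than one sub-threshold voxel. Spill-over
is emulated by an isotropic Gaussian PSF (σ in mm); noise is additive
Gaussian truncated at zero. The generator reports exact ground truth
(painted voxel volume per lesion, supra-threshold volume at a stated
threshold) *before* PSF and noise.

What the phantom does **not** model: reconstruction physics (Poisson
counts, OSEM artifacts, scatter), anthropomorphic anatomy, CT Hounsfield
simulation, respiratory motion, paramedullary soft-tissue disease. A green
ground-truth-recovery test therefore establishes the correctness of the
thresholding/watershed/metric arithmetic, not clinical accuracy.

**Cohort** (`cohort_spec()` / `generate_cohort()`). A Gaussian copula ties
a latent burden to the biopsy infiltration rate and β2-microglobulin with
target Spearman correlations (defaults 0.4/0.4/0.35 — the moderate
correlations such a method exhibits); latent Pearson values are converted
via `2·sin(πρ/6)`. Marginals: infiltration `100·Beta(1.35, 2.2)` (median
≈ 36%), β2-microglobulin log-normal with median 2.7 mg/L, per-approach MTV
log-normal with medians falling from 134.9 mL (Approach 1) to a
zero-inflated strictest approach (55% zeros), matching the skew and the
zero point masses such data show. Lesional SUVmean rises with burden, so
TLG is comonotone with MTV up to noise. Visual groups come from burden
tertiles with a 5% label-noise rate; cytogenetic risk is independent of
burden by design (the association such studies failed to find). With all
noise parameters at 0 and a comonotone copula the generated table is
exactly rank-perfect — the degenerate case the trivial tests pin.

## Statistical conventions

- Ties always take average ranks; zeros from strict approaches enter rank
  tests as ordinary heavy ties.
- Exact enumeration for Wilcoxon and Jonckheere–Terpstra when the pooled
  n ≤ 12 (feasible and deterministic); otherwise normal approximations
  with tie-corrected variance and a 0.5 continuity correction (both
  statistics live on a unit lattice; without the correction the
  approximation misses the exact tail by up to ≈0.06 at n = 12, with it
  the agreement is within 0.02 on continuous data — heavily tied data
  degrade it to ≈0.05).
- Two-sided p values throughout by the doubled-smaller-tail convention;
  one-sided alternatives are available for the trend test. The sidedness
  of the original analyses is not documented; two-sided is the
  conservative declared default.
- Spearman p values use the t approximation on n − 2 df; a constant input
  returns an explicitly `undefined` result, never a silent zero.
- ROC: AUC by the trapezoidal rule over observed thresholds (provably
  equal to the Mann–Whitney probability with half-weighted ties; asserted
  against a pair-counting oracle); the p value against AUC = 0.5 reuses
  the rank-sum test; the CI is a stratified percentile bootstrap (2000
  replicates, seeded) — the CI method of the original analysis is not
  stated, so this is a declared choice. The reported cut point is the
  smallest observed threshold maximizing sensitivity + specificity
  (deterministic; favors sensitivity), with prediction positive at
  score ≥ threshold.
- No multiple-testing correction by default, matching the analysis plan
  the package mirrors (α = 0.05 per test); `p.adjust` can of course be
  applied to any report column downstream.

## Degenerate inputs

Empty infiltration masks flood to zero regions and quantify to zero burden;
empty reference-organ masks are errors (thresholds would be undefined);
single-class labels are an error for ROC; constant vectors are an
undefined-flagged Spearman result; a cohort below 3 rows is rejected.

## Known limitations

- Pure-R watershed: fine for desk-scale grids (a full default phantom
  quantifies in seconds) but not optimized for clinical-resolution masks
  with millions of supra-threshold voxels.
- NIfTI support covers the common single-file cases (datatypes 2, 4, 8,
  16, 64, 256, 512; qform rotations are ignored in favor of sform or
  pixdim). DICOM is out of scope.
- The visual-read surrogate is a fixed rule on component counts and median
  marrow SUV; it does not emulate reader judgment (benign-cause exclusion,
  CT correlation) and is intended for labeling synthetic cohorts.
- Skull, and with it cranial disease, is excluded by design; paramedullary
  soft-tissue extension of bone lesions is outside the skeletal mask and
  is not captured.
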