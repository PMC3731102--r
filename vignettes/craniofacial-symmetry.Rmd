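---
title: "Quantifying craniofacial symmetry from 3D cephalometric landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying craniofacial symmetry from 3D cephalometric landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceph3d)
```

## The method

Cone-beam CT gives 1:1 three-dimensional reconstructions of the skull, so
craniofacial form can be quantified directly from 3D landmark coordinates
instead of projected 2D cephalograms. `ceph3d` implements a landmark-based
3D cephalometric analysis of craniofacial symmetry built on a closed
vocabulary of 12 landmarks: four bilateral pairs — condyle (CdR/CdL),
gonion (GoR/GoL), frontozygomatic point (FzR/FzL) and the ramus/coronoid
point (KrR/KrL) — and four midline points: menton (Me), nasion (N),
glabella (Gl) and a mandibular-body midline point (DB).

From these, 21 inter-landmark Euclidean distances are defined; they are
exactly the sides of 7 diagnostic triangles plus the midline height
Gl–Me:

* three facial/cranial triangles — CdR-Me-CdL, FzR-Me-FzL, GoR-N-GoL;
* four mandibular triangles — the ramus triangles KrR-CdR-GoR and
  KrL-CdL-GoL, and the body triangles DB-Me-GoR and DB-Me-GoL.

All reported quantities are angles, ratios and differences of distances,
so they are invariant under rigid motion of the scanner frame and (for
the ratios and angles) under uniform scale; no Procrustes registration
or orientation convention is needed, and subjects of different ages can
be compared without size correction.

### The semiangle test

The central symmetry statistic works on the condyle–menton triangle
CdR-Me-CdL. Let CdM be the midpoint of the inter-condylar segment
CdR–CdL, and split the apex angle at Me into two semiangles,

$$\alpha_R = \angle\,\mathrm{CdR\text{-}Me\text{-}CdM},\qquad
  \alpha_L = \angle\,\mathrm{CdL\text{-}Me\text{-}CdM} .$$

Because CdM lies on the segment CdR–CdL, the three rays from Me are
coplanar and $\alpha_R + \alpha_L$ equals the full apex angle. The ray
Me→CdM is the median from the apex, and a median bisects the apex angle
exactly when the triangle is isosceles, i.e. when
$|\mathrm{CdR\text{-}Me}| = |\mathrm{CdL\text{-}Me}|$. The absolute
semiangle difference $|\alpha_R - \alpha_L|$ is therefore a direct,
orientation-free index of left–right mandibular symmetry. A subject is
classified *symmetric* when the difference does not exceed a threshold,
4° by default and inclusive at the boundary (a subject at exactly 4° is
symmetric); both the value and the inclusiveness convention are exposed
in `ceph_config()`.

### Ratio systems and millimetric discrepancies

Two ratio systems complement the angular test:

* **Facial ratios.** Perfect proportionality of the three facial
  triangles and the Gl–Me height would put every pairwise ratio of their
  10 distances at 1:1. `facial_ratios()` computes the full closure of
  all 45 unordered pairs, with the numerator taken as the earlier
  distance in registry order so the table is deterministic and each
  entry's inverse is recoverable exactly. The published analysis used a
  subset of these pairs that cannot be reconstructed from the text, so
  the full closure — a superset of any such subset — is computed; a flag
  marks entries deviating from 1 by more than a tolerance (default 0.10,
  an artifact parameter, not a clinical norm).
* **Mandibular ratios.** Nine named ratios compare the sides of the four
  mandibular triangles: five left/right homologue ratios (`R_Kr_Cd`,
  `R_Kr_Go`, `R_Cd_Go`, `R_DB_Go`, `R_Go_Me`, left side in the
  numerator), two within-body ratios (`R_DB_GoL_Me`, `R_DB_GoR_Me`) and
  two base ratios of ramus base against the body base DB–Me
  (`R_KrL_CdL_DB_Me`, `R_KrR_CdR_DB_Me`).

Finally, `lr_discrepancy()` compares three left/right homologue pairs in
millimetres (FzR-Me vs FzL-Me, GoR-N vs GoL-N, CdR-Me vs CdL-Me) and
classifies the subject by whether the largest absolute difference stays
within 5 mm (inclusive; configurable).

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `semiangle_threshold_deg` | degrees | 4 | inclusive symmetry call on the semiangle difference |
| `discrepancy_threshold_mm` | mm | 5 | inclusive call on the max left-right distance gap |
| `ratio_tolerance` | — | 0.10 | flags facial ratios away from 1:1 |
| `sd_estimator` | — | `"sample"` | cohort sd denominator (n−1, or n for `"population"`) |
| `noise_sd` (generator) | mm | 0.4 | digitization noise, one scanner voxel edge |
| `asym_magnitude_range` (generator) | mm | (8, 14) | deformation magnitude of asymmetric subjects |

## Numerical choices

* Angles are computed from the clamped cosine of the ray directions:
  the cosine is pinned to [−1, 1] before `acos`, so collinear landmark
  triples yield exactly 0° or 180° instead of NaN.
* The degeneracy tolerance is 10⁻⁹ mm — far below any digitization
  error (the voxel is 0.4 mm) — and is used to refuse coincident
  landmarks and zero-length rays.
* If Me is collinear with the inter-condylar line, the semiangle result
  is *flagged* degenerate rather than raised as an error, so cohort runs
  survive pathological subjects; flagged subjects are excluded from
  angle-based cohort statistics and tallied in `excluded`. In the
  extreme sub-case where Me coincides with CdM the semiangles are
  undefined and reported as `NA`.
* Missing landmarks fail loudly at analysis time (listing the missing
  codes) instead of propagating NaN, which would silently corrupt
  cohort percentages; loading, by contrast, accepts incomplete sets so
  that partial digitizations can still be inspected and validated.
* Landmark files are written at 17 significant digits, so a write/load
  round trip reproduces coordinates bit-for-bit in all three formats
  (package CSV dialect, 3D Slicer FCSV, JSON).

## The synthetic cohort generator

No landmark cohort is distributed with the package, so validation rests
on `generate_cohort()`, which produces cohorts with known ground truth.
The base object is `symmetric_template()`: a fixed, exactly
mirror-symmetric configuration (right landmarks at +x, left at −x,
midline at x = 0) whose 21 distances all fall in plausible adult ranges
(about 41–128 mm, e.g. inter-condylar width 120 mm, apex angle at Me
about 64°). The template's coordinates are artifact constants chosen for
anatomical plausibility, not population means.

Asymmetric subjects receive a *hemimandibular elongation* pattern of
magnitude *m* drawn uniformly from `asym_magnitude_range`: the chin
point Me deviates laterally by *m* toward the affected side while the
contralateral condyle is elongated by *m* along its ray from Me — the
geometry of unilateral condylar overgrowth. On the template this induces
a semiangle difference of about 0.6°/mm, so the default range (8–14 mm)
yields true differences of roughly 5–8.5° and millimetric discrepancies
of 16–29 mm. Both sit well clear of the 4° / 5 mm thresholds compared
with the angular scatter produced by voxel-scale digitization noise
(sd ≈ 0.14° at `noise_sd = 0.4` mm), so noise essentially never flips a
classification; the range was fixed once on this calibration and is a
generator default, not a fitted value. A pure chin deviation alone, by
contrast, changes the semiangle by only ≈ 0.33°/mm — deviations that
stay in the clinically mild range leave the angle under the threshold —
which is why the combined pattern is the default deformation.

Truth labels (`symmetric` iff both noise-free criteria hold) are
computed on the deformed geometry *before* noise injection; symmetric
subjects are exact copies of the template, so their true semiangle
difference and discrepancies are identically zero. The generator uses a
single seeded random stream, records the seed in its output metadata,
and balances labels deterministically: the symmetric count is
`round(n * symmetric_fraction)`.

What the generator does **not** emulate: correlated placement error
(real observers err along anatomical ridges, not isotropically), growth-
and age-structured shape variation, occlusion-state differences, and the
milder, multi-regional asymmetries of real patients. Passing tests on
synthetic cohorts therefore demonstrate the correctness of the
*computations* and the recoverability of *injected* effects at realistic
noise, not clinical classification accuracy.

## Cohort statistics

`summarize_cohort()` reports the sample mean and sample (n−1) standard
deviation of each of the 21 distances, min/max/mean of every ratio, and
the two prevalence percentages. The sd estimator is configurable because
the choice is a convention, not a result; percentages are kept unrounded
internally and displayed at 2 decimals. Prevalences are computed over
the subjects assessable for the criterion (degenerate-flagged subjects
are excluded from the angular prevalence and counted).

Problem sizes used by the packaged validation suite and the
reproduction script — 1000 random configurations for the brute-force
equivalence sweep, 300-subject cohorts for prevalence recovery, 60
subjects for exact noise-free recovery — were chosen so that binomial
and Monte-Carlo error are small relative to the effects checked.

## Known limitations

* The anatomical prose definitions of the landmark points are available
  only as an image in the source literature; the package fixes the codes
  and laterality but cannot ship the full prose definitions.
* The facial ratio table is a documented superset (all 45 pairs) of the
  originally reported subset; the mandibular ratio set, by contrast, is
  reproduced exactly as named.
* Cohort-level percentages depend entirely on the cohort analyzed;
  the package makes no claim about population norms.
* FCSV support covers the fiducial markup dialect (one subject per
  file); curves and other markup types are out of scope, as are DICOM
  ingestion and landmark digitization themselves.
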