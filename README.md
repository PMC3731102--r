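# ceph3d — 3D cephalometric craniofacial symmetry analysis

`ceph3d` quantifies craniofacial symmetry from 3D cephalometric landmark
coordinates, as digitized on cone-beam CT (CBCT) reconstructions. It is
aimed at orthodontists, maxillofacial researchers and morphometricians
who have per-patient tables of named landmark coordinates (from InVivo,
3D Slicer or similar) and want reproducible, orientation-free symmetry
indices for diagnosis, treatment planning or cohort studies.

## The method

Twelve landmarks — bilateral condyle (CdR/CdL), gonion (GoR/GoL),
frontozygomatic (FzR/FzL) and ramus/coronoid (KrR/KrL) points, plus
midline menton (Me), nasion (N), glabella (Gl) and a mandibular-body
point (DB) — define 21 inter-landmark distances, which are exactly the
sides of 7 diagnostic triangles plus the midline height Gl–Me.

The headline statistic is the **semiangle test** on the condyle–menton
triangle CdR-Me-CdL. With CdM the midpoint of CdR–CdL, the apex angle at
Me splits into two semiangles

α_R = ∠CdR-Me-CdM,  α_L = ∠CdL-Me-CdM,  α_R + α_L = ∠CdR-Me-CdL,

and the median Me→CdM bisects the apex exactly when |CdR-Me| = |CdL-Me|
(isosceles ⟺ symmetric mandible). A subject is called symmetric when
|α_R − α_L| ≤ 4° (inclusive, configurable). This is complemented by

* **facial ratios** — all 45 pairwise ratios of the 10 distances of the
  three facial triangles and Gl–Me, each ideally 1:1;
* **nine mandibular ratios** (`R_Kr_Cd` … `R_KrR_CdR_DB_Me`) comparing
  the sides of the two ramus and two body triangles;
* **millimetric discrepancies** — |FzR-Me − FzL-Me|, |GoR-N − GoL-N|,
  |CdR-Me − CdL-Me|, classified against a 5 mm maximum (inclusive).

Every reported quantity is a ratio, angle or difference of distances, so
results are invariant under rigid motion of the scanner frame and
independent of patient age or size. `generate_cohort()` simulates
labeled synthetic cohorts (mirror-symmetric template, parametric
asymmetry, voxel-scale digitization noise) for end-to-end validation.
See the vignette `vignettes/craniofacial-symmetry.Rmd` for the model,
parameters and numerical choices.

## Worked example

```r
library(ceph3d)

f <- system.file("extdata", "synthetic_cohort.csv", package = "ceph3d")
cohort <- load_landmarks(f, "csv")     # 4 synthetic subjects
rep <- analyze_patient(cohort[[2]])
print(rep)
#> <patient_report> subject 'sim0002'
#> <semiangle> full 63.960 deg; R 31.798 / L 32.163; diff 0.365 deg -> symmetric
#> <discrepancy> Fz 0.45, Go 0.33, Cd 1.15 mm; max 1.15 -> within threshold
#>   facial ratios flagged (|r-1| > 0.10): 17 of 45
```

Subject `sim0002`'s apex angle at menton is 63.96°, split into 31.80°
(right) and 32.16° (left); the 0.37° difference is far below the 4°
threshold and the largest left–right distance gap (condyle–menton,
1.15 mm) is below 5 mm, so the subject is symmetric by both criteria.
The flagged facial ratios are the pairs involving the wide
inter-condylar distance CdR-CdL, which does not approach 1:1 against
the other facial distances even in symmetric subjects.

```r
summ <- summarize_cohort(lapply(cohort, analyze_patient))
print(summ)
#> <cohort_summary> n = 4
#>   semiangle-symmetric: 50.00%
#>   within discrepancy threshold: 50.00%
#>   measurements (first 5 of 21):
#>      code mean_mm sd_mm
#> 1  CdR-Me  115.93  8.96
#> 2  CdL-Me  115.54  8.19
#> 3 CdR-CdL  122.52  2.92
#> 4  FzR-Me  121.78  3.61
#> 5  FzL-Me  121.49  2.97
```

This example file was generated with
`generate_cohort(4, symmetric_fraction = 0.5, ...)`, so half the
subjects carry an injected mandibular asymmetry — the 50% prevalences
recover the construction.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ceph3d.R", package = "ceph3d"))')
Rscript "$CLI" simulate --n 300 --symmetric-fraction 0.7 --noise-sd 0.4 \
                        --seed 17 --out sim/
Rscript "$CLI" analyze  --input sim/cohort.csv --format csv --out results/
```

`analyze` writes `patients.csv`, `patients.json`, `cohort_summary.json`
and per-table CSVs; exit status 0 on success, 2 on usage/input errors.

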