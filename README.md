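# ithmri

Habitat-based quantification of intratumoral heterogeneity (ITH) from
MRI tumor regions of interest, with downstream evaluation of the score
as a non-invasive marker of HER2 status in breast cancer.

## The problem and the method

HER2-positive breast cancer is eligible for targeted therapy, but HER2
status is established by biopsy. Intratumoral heterogeneity — the
diversity of cell composition and spatial organization within one tumor
— is visible in DCE-MRI as spatial variation of enhancement texture, and
is elevated in HER2-positive disease. `ithmri` turns a tumor ROI into a
single ITH score in four steps:

1. read the NIfTI image/mask pair, keep the index lesion (largest
   26-connected component), resample to an isotropic 1 mm grid, and
   z-score the ROI;
2. extract local first-order and GLCM texture features with a 3 × 3 mm
   sliding window on the largest-area slice;
3. cluster the per-pixel feature vectors (per tumor, k-means, default
   k = 6) into a habitat label map;
4. score the spatial fragmentation of that map. With `n_i` the number of
   connected regions of habitat `i` and `S_i,max` the area of its
   largest region,

   ```
   ITH = 1 - (1 / S_total) * sum_i  S_i,max / n_i
   ```

   so a tumor whose habitats are each one connected territory scores 0,
   and a tumor shattered into many small subregions approaches 1.

The statistics stage relates per-patient ITH to HER2: point-biserial
(Pearson) correlation, ROC analysis of ITH alone and combined with age
(logistic model with nomogram export; boosted trees optional),
per-site and age-subgroup analyses, and a train-on-site-1 /
validate-on-site-2 external validation. A synthetic two-site cohort
generator with a known latent heterogeneity–label association makes the
whole pipeline testable end to end without patient data.

## Worked example

```r
library(ithmri)

# one synthetic tumor, fairly heterogeneous (latent h = 0.8)
spec <- generator_spec()
vol <- make_tumor(spec, heterogeneity = 0.8, seed = 7, patient_id = "demo")
vol
#> tumor_volume 'demo' (site hospital1): 64x64x5 grid, spacing 1x1x1 mm, 1080 ROI voxels

ith_pipeline(vol)
#> ith_result 'demo': ITH = 0.9544 (V = 6 habitats, S_total = 568 px, 8-connectivity)
```

The score 0.95 says the analysis slice (568 px) splits into 6 habitats
whose territories are heavily fragmented — consistent with the tumor's
high latent heterogeneity. A homogeneous tumor
(`make_tumor(spec, 0, ...)`) scores 0.

A small two-site cohort, scored and analyzed:

```r
spec <- generator_spec(n_per_site = c(60L, 60L), seed = 42)
cohort <- make_cohort(spec)
scored <- score_cases(cohort$cases)
tab <- merge(cohort$table, scored[, c("patient_id", "ITH")], by = "patient_id")
run_study(tab)
#> ith_study_report: n = 120, Pearson r = 0.5725 (p = 8.38e-12)
#>   ITH alone:    AUC 0.862 (sens 0.900, spec 0.786)
#>   ITH + age:    AUC 0.864 (sens 0.880, spec 0.786)
#>   site hospital1: AUC 0.848 (n = 60)
#>   site hospital2: AUC 0.983 (n = 60)
#>   external val: AUC 0.983 (train hospital1, n = 60 -> validate n = 60)
```

Here the positive Pearson r (point-biserial, since HER2 is binary) and
the AUCs quantify how well the ITH score separates HER2-positive from
HER2-negative patients overall, per site, and on the held-out site.

## Command line

```sh
inst/cli/ith-mri simulate --profile small --out fixtures/
inst/cli/ith-mri score    --manifest fixtures/manifest.csv --out scores/
inst/cli/ith-mri analyze  --cohort scores/ith_scores.csv --out report/
```

`score` writes `ith_scores.csv` plus an `exclusions.csv` listing cases
that failed a stage (e.g. degenerate ROI) with the reason; `analyze`
writes `report.json`, metric tables, ROC plots, and nomogram
coefficients.

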