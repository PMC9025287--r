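# habitatmri

Perfusion habitat imaging and survival risk modelling for breast DCE-MRI.

## What it does, and for whom

Breast tumors are perfusionally heterogeneous: subregions of the same
tumor enhance and wash out contrast material at different rates, and the
*spatial arrangement* of those subregions carries prognostic information
that whole-tumor radiomics averages away.  `habitatmri` is for imaging
scientists who want to run — or stress-test — a habitat analysis of
three-phase dynamic contrast-enhanced (DCE) MRI end to end:

1. **Perfusion maps.** From the pre-contrast, early and delayed phases,
   each voxel gets a kinetic triplet
   `E_in = I_early − I_pre`,
   `E_out = I_early − I_delayed`,
   `R_WO = (I_early − I_delayed)/I_early` if `I_delayed < I_early`, else 0.
2. **Habitat discovery.** The triplets of *all* development-cohort tumor
   voxels are quantized (256 bins per feature) and clustered together by
   k-means (k-means++ restarts, Lloyd iterations, Euclidean distance).
   The number of habitats is selected from repetition-averaged
   Calinski-Harabasz and silhouette diagnostics over k = 2..32, and the
   development centers are propagated verbatim to the validation cohort.
3. **Heterogeneity features.** Each patient's habitat label map is
   summarized by 58 features — 4 histogram, 24 GLCM, 16 GLSZM
   (IBSI/PyRadiomics definitions, habitat labels as gray levels) and 14
   mesh-based shape features — plus the per-habitat volume fractions.
4. **Habitat risk score.** A cross-validated Cox-LASSO on the z-scored
   features yields `HRS_i = h0(0) · exp(Σ_j β_j x_ij)`; the development
   median splits patients into risk groups, and five risk models
   (two conventional whole-tumor radiomics panels, HRS-only, clinical,
   combined) are compared by hazard ratio and Harrell's C.

Patient MRI cannot be redistributed, so the package ships a synthetic
dual-cohort generator (`simulate_cohort`, `simulate_pfv_cohort`) that
plants five kinetic habitat archetypes at fixed mixing proportions,
renders three-phase volumes on anisotropic grids with different scanner
characteristics per cohort, and drives survival from planted Cox
coefficients on the habitat-heterogeneity features.  Every stage is
testable against that ground truth.

## Worked example: recovering planted habitats

Draw 50,000 tumor voxels from the five-habitat mixture, quantize, and
cluster at the cohort level:

```r
library(habitatmri)

spec <- cohort_spec(seed = 7)                     # archetype kinetics + proportions
pf   <- simulate_pfv_cohort(spec, n_voxels = 50000)
qz   <- fit_quantizer(pf$pfv)                     # 256-bin quantizer per feature
xq   <- apply_quantizer(qz, pf$pfv)
fit  <- population_kmeans(xq, k = 5, n_reps = 10, seed = 7)
fit
#> Habitat model: k = 5 perfusion habitats
#>                ein     eout   rwo
#> habitat_1  825.436 -666.955 0.033
#> habitat_2 1150.116  332.774 0.337
#> habitat_3 1260.119  771.373 0.533
#> habitat_4 2203.814  -13.445 0.076
#> habitat_5 2415.753  867.411 0.359
```

Rows are the recovered cluster centers in raw intensity units (wash-in,
washout, washout ratio), in canonical order of ascending wash-in.
Cluster numbering is arbitrary, so compare to the planted archetypes by
bipartite matching and read off the recovered occupancy of each planted
habitat:

```r
ref  <- as.matrix(default_habitat_kinetics()[, c("ein", "eout", "rwo")])
perm <- match_centers(fit$centers, ref)           # cluster i -> archetype perm[i]
prop <- tabulate(fit$cluster, 5) / length(fit$cluster)
matched <- numeric(5); matched[perm] <- prop
round(100 * matched, 1)
#> [1] 41.7  6.8 25.8 21.2  4.4
```

The planted mixing proportions were 41.9, 6.8, 25.6, 23.5 and 2.2
percent: the dominant persistent-enhancement habitat (1) and the
strong-wash-in plateau habitat (3) are recovered within a fraction of a
percentage point, and the recovered wash-in center of the
strongest-enhancing archetype (2416 vs 2420) is within 0.2%.  The only
appreciable leakage is between archetypes 4 and 5, the two closest
centers — the rare marked-washout habitat borrows voxels from its
moderate-washout neighbor, which is exactly the regime the
cluster-number diagnostics have to resolve.

The full staged pipeline (synthetic cohorts → preprocessing → perfusion
→ habitats → features → Cox-LASSO → five-model report) runs from one
config:

```r
cfg <- pipeline_config("habitat_run", seed = 1, n_dev = 20, n_val = 10)
run_pipeline(cfg)    # artifacts + resolved config + log under habitat_run/
```

or from the shell via `Rscript inst/cli/habitatpipe.R all --out habitat_run`.

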