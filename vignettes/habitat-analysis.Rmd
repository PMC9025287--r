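---
title: "Perfusion habitat analysis of breast DCE-MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion habitat analysis of breast DCE-MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Invasive breast tumors are perfusionally heterogeneous: different
subregions of the same tumor wash contrast material in and out at
different rates, and that spatial organization carries prognostic
information that whole-tumor summary statistics blur away.  `habitatmri`
implements a habitat-imaging analysis of three-phase dynamic
contrast-enhanced (DCE) MRI: it maps each tumor voxel into a perfusion
feature space, discovers a small number of recurring kinetic phenotypes
("habitats") across a whole cohort, and quantifies how heterogeneously
those habitats are arranged inside each tumor.  The heterogeneity
summary is then compressed into a single habitat risk score (HRS) whose
median split stratifies disease-free survival (DFS).

This vignette explains each model in the chain, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical decisions that make the pipeline
reproducible.

# Perfusion maps

From the pre-contrast, early-phase and delayed-phase T1-weighted
volumes, three voxelwise kinetic maps are derived:

* wash-in: $E_{in} = I_{early} - I_{pre}$,
* washout: $E_{out} = I_{early} - I_{delayed}$ (negative values mean
  persistent late enhancement),
* washout ratio:
  $R_{WO} = (I_{early} - I_{delayed})/I_{early}$ if
  $I_{delayed} < I_{early}$, and $0$ otherwise ("no washout").

$R_{WO}$ is additionally defined as 0 where $I_{early} = 0$, so the map
is total on clipped non-negative intensities; this situation cannot
arise from the strict-inequality branch anyway.  The triplet
$(E_{in}, E_{out}, R_{WO})$ of a voxel is its perfusion feature vector
(PFV).

# Preprocessing

Cohorts are acquired at anisotropic resolutions (about
$0.85 \times 0.85 \times 3$ mm), so all volumes are first resampled to
1 mm isotropic resolution with interpolating cubic B-splines (the
recursive prefilter with pole $\sqrt3 - 2$ and mirror boundaries, then
separable kernel evaluation).  ROI masks use nearest-neighbor
interpolation and stay binary.  B-spline overshoot near sharp edges is
clipped at zero because negative MR magnitudes are non-physical.

Because the two cohorts come from different scanners with different
intensity characteristics, the validation cohort is harmonized by
histogram matching: a 256-point quantile table per phase is pooled over
the development cohort's ROI voxels, and each validation study's
quantiles are mapped onto it by monotone piecewise-linear interpolation.
The mapping is *estimated* from tumor voxels only — tumor intensities
are what feed clustering, and background air would otherwise dominate
the mapping — but *applied* to the whole volume; out-of-range values
clamp to the reference extremes.  Matching is idempotent up to
quantization, and monotonicity preserves intensity rank order.
Whole-image versus tumor-only estimation is configurable; tumor-only is
the default.

# Habitat discovery

Each PFV feature is quantized on a uniform 256-bin grid spanning the
development cohort's pooled minimum to maximum (values are replaced by
their bin centers; the last bin is right-closed so the maximum lands in
it).  Quantization stabilizes the clustering against extreme voxels and
fixes the resolution at which centers are reported.

Clustering is applied at the *cohort* level — the PFVs of all
development patients are pooled — so habitat labels are directly
comparable across patients.  `population_kmeans()` runs Lloyd's
algorithm (Euclidean distance) from k-means++ initializations, one seed
per repetition, and retains the repetition with the lowest
within-cluster inertia.  Features are clustered in raw quantized units
without per-feature standardization: habitat centers are meant to be
read in raw intensity units (wash-in on the order of $10^3$, washout
ratio at most 1), and that convention is what makes the reported
centers interpretable.  A `standardize` flag exists for sensitivity
analyses but defaults to off.

The number of habitats is selected by sweeping $k = 2..32$ with 100
scored repetitions per $k$ (defaults; tests and examples scale these
down).  Two diagnostics are averaged over repetitions:

* Calinski-Harabasz score $[B/(k-1)]/[W/(n-k)]$, computed on the full
  pooled data;
* mean silhouette $(b-a)/\max(a,b)$, computed exactly when the pool is
  small and otherwise on a seeded subsample (default 2000 voxels,
  configurable up to the documented 10,000 cap).  The silhouette is
  quadratic in the number of voxels and cohort pools reach millions, so
  subsampling is a deliberate, documented deviation; at 2000 voxels the
  Monte-Carlo error of the mean silhouette is well below the
  between-$k$ differences that drive selection.

`select_k()` picks the last $k$ before the averaged CH score starts a
sustained decrease (the smallest $k$ whose score is never exceeded at
any larger $k$).  Agreement with the silhouette top two is checked and a
disagreement is warned, but the CH knee is kept.  This asymmetry is
deliberate: the mean silhouette is an average over voxels, so a rare
habitat (a few percent of the pool) contributes almost nothing to it
and merging that habitat into a neighbor typically *raises* the mean
silhouette; the CH score's between-cluster scatter still registers the
rare cluster's centroid.  Letting silhouette override CH would
therefore bias selection toward merging exactly the small, aggressive
subregions the analysis is after.  Ties resolve to the smaller $k$.
Two degenerate regimes are handled explicitly: a CH curve still
increasing at the largest candidate returns that candidate with a
warning, and a best mean silhouette below 0.5 (the usual reading of "no
substantial structure") returns the smallest candidate with a
weak-structure warning — on unstructured clouds the CH knee is noise,
as a single Gaussian cloud readily demonstrates.

Validation cohorts never re-cluster: the development centers and
quantizer are propagated verbatim, and each ROI voxel takes the label
of its nearest center (ties to the lowest canonical label; canonical
order sorts centers by ascending wash-in, then washout).  Cluster
numbering out of k-means is arbitrary, so all comparisons against a
reference table go through exhaustive bipartite center matching
(`match_centers()`).

# Heterogeneity features of the habitat map

The habitat map (labels $1..k$ inside the ROI, 0 outside) is summarized
by 58 features plus the $k$ habitat proportions:

* 4 first-order histogram features of the label distribution at bin
  size one: entropy (bits), uniformity, skewness and (uncorrected)
  kurtosis.  The identity of the four histogram features is
  configurable; since a label histogram has no meaningful intensity
  scale, this entropy/uniformity/shape set is the natural default.
  For a constant map, skewness and kurtosis are defined as 0.
* 24 gray-level co-occurrence (GLCM) features at distance 1 over the 13
  unique 3D directions, matrices symmetrized, feature values averaged
  over directions (averaging features, not matrices, is the common
  radiomics default and is the documented switch).  Degenerate
  single-label conventions: correlation 1, IMC1 0, MCC 1.
* 16 gray-level size-zone (GLSZM) features with zones defined as
  26-connected components of equal label.
* 14 3D shape features of the ROI: mesh volume, voxel volume, surface
  area, surface-to-volume ratio, sphericity, maximum 3D and per-plane
  2D diameters, PCA axis lengths, elongation and flatness.

Habitat labels act directly as gray levels ("bin size one"), so the
gray-level count equals $k$.

Surface area and mesh volume come from a marching-tetrahedra
iso-surface at level 0.5.  Meshing the *binary* mask with midpoint
vertices overestimates the area of smooth shapes substantially (the
jagged diagonal facets add ~25% for a 10 mm digital ball), so the mask
is first smoothed with a separable Gaussian (SD 1 voxel) and vertices
are placed by linear interpolation along tetrahedron edges; on the
10 mm ball this lands within ~1.5% of the analytic surface area, and
the surface-to-volume ratio is within 5% of its analytic limit $3/r$.
Masks too small to mesh fall back to voxel-face estimates and carry a
`voxel_fallback` flag.

The two conventional whole-tumor comparators reuse the same texture
machinery after discretizing a continuous image inside the ROI with a
fixed bin count (default 32).  The 72-feature panels are composed as
24 GLCM features per image over the three phase images
(`radiomics_DCE_MR`) or the three perfusion maps
(`radiomics_perfusion`); the composition is configurable
(`panel = "all"` adds GLSZM and histogram blocks).

All features are z-score normalized with the *development* cohort's
mean and SD — the validation cohort is normalized with the development
statistics, never its own.  Constant features are dropped with a
warning.

# The habitat risk score and the five risk models

The HRS is built by an L1-penalized Cox proportional-hazards fit
(Cox-LASSO, Breslow tie handling) on the z-scored habitat features.
The penalty is chosen by 10-fold cross-validated partial-likelihood
deviance over a 50-point log grid with folds stratified by event
status, followed by a refit on all development data at the selected
penalty; a fully nested outer evaluation loop is available behind a
flag but is not the default, since only the selected model is
propagated.  The score of patient $i$ is the relative hazard at time
zero,

$$HRS_i = h_0(0)\, e^{\sum_j \beta_j x_{ij}},$$

where $h_0(0)$ is taken as the Breslow baseline-hazard increment at the
earliest development event time.  $h_0(0)$ is a patient-independent
positive constant, so ranking, median split and every downstream
statistic are invariant to this choice; it is recorded in the model
metadata for transparency.

Patients are split at the *development median* of each risk score
(scores exactly at the cutoff go to the high-risk group; the convention
is fixed for bit-reproducibility) and the same cutoff is reused for the
validation cohort.  Five models are built and evaluated per cohort:
`radiomics_DCE_MR`, `radiomics_perfusion`, `HRS_only`, `clinical` (the
encoded clinicopathological/radiological covariate panel) and
`combined_habitat` (clinical + HRS).  Each reports the high-vs-low
hazard ratio with Wald CI and p-value, Harrell's C-index with its SE,
and a comparison p-value against the combined model computed by a
bootstrap paired-t procedure: patients are resampled with replacement,
both C-indices recomputed per replicate, and a paired t statistic taken
over replicate differences.  The exact comparison test behind the
published analysis is not specified beyond "paired t-test on
C-indices", so this resampling version is the package's documented
stand-in.

# The synthetic cohort generator

Real patient volumes cannot be redistributed, so the generator builds
cohorts with the statistical structure the analysis assumes; it is
first-class, tested code, not a fixture.

* **Tumors** are rasterized ellipsoids (radius drawn from 6–14 mm, mild
  random flattening) centered in a field of view with an 8 mm
  background margin, on the cohort's native anisotropic grid
  (development $0.85 \times 0.85 \times 3$ mm, validation
  $0.80 \times 0.80 \times 3$ mm, so resampling is always exercised).
* **Habitat label fields**: with `spatial_clump = 0` labels are i.i.d.
  multinomial draws at the target proportions; with a positive
  correlation length one smoothed Gaussian random field per habitat is
  standardized, shifted by a numerically calibrated offset, and the
  voxel takes the argmax habitat.  The offsets solve the
  argmax-of-Gaussians win-probability equations, so marginal
  proportions equal their targets for any clump length while patches
  stay spatially contiguous.
* **Rendering** inverts the perfusion-map definitions:
  $I_{pre} = 500 + \epsilon$, $I_{early} = I_{pre} + E_{in} +
  \epsilon$, $I_{delayed} = I_{early}(1 - R_{WO}) + \epsilon$, clipped
  at zero, with $(E_{in}, R_{WO})$ taken per habitat from the archetype
  table.  The five archetypes (wash-in 825, 2420, 2206, 1154, 1302;
  washout ratios 0.021–0.717; mixing proportions 0.419, 0.068, 0.256,
  0.235, 0.022) span the canonical kinetic patterns: persistent low
  enhancement, strong wash-in with washout, strong wash-in plateau,
  moderate wash-in washout, and marked washout.  The archetype table
  also carries a washout column for the bare-PFV mode; note that a
  centroid of a ratio is not the ratio of centroids, so the rendered
  washout of a habitat derives from $R_{WO} \cdot I_{early}$ rather
  than from that column.  Background voxels get low, persistent
  enhancement (|N(50, 30)|) so histogram matching has realistic
  support.
* **Dispersion defaults**: bare-PFV per-feature SDs (150, 150, 0.05)
  and rendered intensity noise SD 60.  These were chosen once as a
  realistic within-habitat spread — roughly a quarter of the smallest
  between-center separation, matching the visible overlap of habitat
  feature distributions in clinical cohorts — and are part of the
  study conditions, not tuning knobs.
* **Validation scanner effect**: a strictly monotone quadratic
  intensity map ($150 + 0.85 I + 3\times10^{-5} I^2$) is applied to all
  three phases, so ROI rank order is preserved and histogram matching
  can undo it.
* **Outcomes**: clinical covariates are drawn at fixed marginal
  frequencies typical of a development cohort; survival times are
  exponential under a proportional-hazards model,
  $T = -\log(U)/(h_{base} e^{LP})$, with $LP$ combining planted
  coefficients on z-scored habitat features (defaults: SVR $-0.235$,
  IDMN $-0.032$, IMC1 $0.017$, small-area emphasis $0.123$) and on
  encoded clinical covariates, administratively censored at 108
  months.  The default baseline hazard (0.0014/month) reproduces a
  realistic ~11% event rate; test configurations raise it so small
  cohorts reliably contain events.

What the generator does *not* emulate: breast anatomy, B0/B1 artifacts,
motion, partial-volume edge effects, pharmacokinetic (Tofts-type)
enhancement curves, or inter-series misregistration (volumes are
aligned by construction, so the affine co-registration step of a
clinical pipeline is out of scope).  Passing tests therefore
demonstrate that the *statistical machinery* recovers planted structure
under realistic noise — not that the pipeline is robust to acquisition
artifacts of real scanners.

# Numerical choices and degenerate inputs

* Lloyd iterations cap at 300 per repetition; repetitions whose
  initialization collapses (an empty cluster) are redrawn from a
  derived seed, up to three times.
* Quantizer: out-of-range validation values clamp to the extreme bins;
  a constant feature degenerates to a single bin with a warning.
* Silhouette of a singleton-cluster point is 0; the CH score of an
  all-singleton partition is NA (documented degenerate case).
* Nearest-center ties go to the lowest canonical label.
* `fit_cox_lasso` with a single supplied penalty skips cross-validation
  (a penalty of 0 gives the unpenalized fit, which matches an
  independent Newton solver to $10^{-6}$); an event-free cohort is an
  error.
* Scores exactly at the median cutoff are high-risk.
* All randomness flows from explicit integer seeds through a splitmix
  style derivation (`derive_seed`), so every artifact is bit
  reproducible given the master seed; seeded code restores the caller's
  RNG state.

# Problem sizes used by the test-suite and acceptance runs

The shipped tests run the cluster-number sweep on a 100,000-voxel pooled
mixture with 20 repetitions per candidate $k$ (the structure-recovery
experiments), end-to-end pipeline checks on 8–20-patient dual cohorts
with a narrowed $k$ sweep, and coefficient-recovery simulations at
$n = 300$ with 40% events over 20 seeds.  These sizes were chosen so the
full suite exercises every stage at statistically meaningful scale on a
single CPU; the package defaults (100 repetitions, $k$ up to 32) match
the full-scale analysis protocol.

# Known limitations

* GLCM/GLSZM definitions follow the IBSI/PyRadiomics conventions, but
  only the feature sets listed above are implemented — no wavelet/LoG
  filtered variants and no 2D (per-slice) texture.
* The silhouette is subsampled (documented above); exact values are
  available for pools up to the configured cap.
* Harrell's C standard error is the concordance estimator's
  infinitesimal-jackknife SE, not the classical pairs-count formula.
* The bootstrap model-comparison p-value is a stand-in for an
  unspecified published procedure and should be read as approximate.
* One patient = one tumor; index-lesion selection for multifocal
  disease is out of scope.
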