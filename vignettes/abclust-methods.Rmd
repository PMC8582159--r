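---
title: "Methods: spatially informed amyloid-PET classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially informed amyloid-PET classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`abclust` treats an amyloid-β PET cohort as a collection of SUVr volumes on
one common template grid, with each subject labelled CN, EMCI, LMCI or AD.
The pipeline's premise is that the diagnostic signal lies not only in how
*much* tracer binds but in *where*: amyloid-positive territory expands
through characteristic brain regions as disease advances, so features that
count positive voxels within data-driven spatial clusters discriminate AD
from CN better than a single global composite SUVr.

The stages, and the assumptions each one makes:

1. **SUVr quantification** divides each volume by its mean over a
   cerebellar grey-matter reference mask. Assumption: the reference region
   is amyloid-free at every stage, so the ratio removes global scanner and
   dose effects. The operation is exactly scale-invariant; applying it to
   data that are already SUVr-scaled is harmless.
2. **Group statistics** are voxel-wise means and sample SDs (n − 1
   denominator — the groups are samples from a population, and the choice
   is recorded in the output metadata) over the GM mask. z-score maps
   compare each clinical group with controls voxel-by-voxel:
   z = (group mean − CN mean)/CN SD. Voxels with zero control SD are
   *excluded* from the validity mask rather than clamped: an infinite or
   clamped z would silently distort downstream thresholds.
3. **The AD-variance mask** keeps voxels satisfying *both* AD-group mean
   SUVr ≥ 1.1 and AD z > 0, then removes connected components below 10
   voxels. The double criterion deliberately honours the two readings of
   "binarised mask at SUVr threshold 1.1 of the AD z-score voxels": each
   threshold is configurable, and setting one to its floor degenerates to
   the other single-criterion reading. De-noising is a component-size
   filter with face (6-)connectivity by default; 6-connectivity is the
   conservative choice because diagonal adjacency tends to bridge noise
   speckle into spuriously large components.
4. **Voxel clustering** partitions the masked voxels by k-means for
   k = 2…13. The clustered items are voxels; each voxel's feature vector
   is, by default, its across-subject SUVr profile
   (`representation = "subject_profile"`). The alternative scalar reading
   (`"voxel_mean"`, each voxel reduced to its across-subject mean) is
   implemented and selectable; the profile representation is the default
   because the output is a single spatial label map and the clusters must
   reflect covariation across the cohort, which a per-voxel scalar cannot
   express. The choice is recorded in the provenance file.
5. **Features and classification.** Per subject: positive-voxel counts
   (SUVr strictly > 1.1) within clusters 1–4 and within GM, GM mean SUVr,
   composite-ROI SUVr and WM mean SUVr. The classifiers compared are a
   quadratic (degree-2 polynomial) SVM on six features, the same SVM on
   the four cluster counts, and logistic regressions on the composite
   SUVr alone and on the two GM features, all under stratified 20-fold
   cross-validation with shared fold assignments so the comparison is
   paired.
6. **Clinical associations.** MMSE within ±183 days and CDR within ±92
   days of the scan (six and three calendar months, converted to days and
   configurable); when several scores qualify the nearest-dated wins,
   ties to the earlier. Distribution summaries use the median, the IQR
   with linear-interpolation quantiles, and skewness g1 = m3/m2^(3/2)
   computed from population moments (the adjusted G1 differs by a factor
   of √(n(n−1))/(n−2) and is not what descriptive tables of this kind
   label "g1"). Pearson correlations carry two-sided p-values from the
   t transform with n − 2 degrees of freedom.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `suvr_threshold` | 1.1 | SUVr | conventional florbetapir positivity cut-point |
| `z_threshold` | 0 | z units | any positive deviation from controls qualifies |
| `min_component_voxels` | 10 | voxels | smallest cluster of biological interest at 4 mm |
| `connectivity` | 6 | — | face adjacency; avoids bridging speckle |
| `positivity threshold` | 1.1 | SUVr | strict ">"; boundary-exact values do not count |
| `k_min..k_max` | 2–13 | — | the swept model orders; 90 division masks |
| `k_select` | 4 | — | the parsimonious model used for features |
| `n_restarts` | 25 | — | see "Numerical choices" |
| `max_iterations` | 1000 | — | Lloyd iteration cap; fixpoint usually < 50 |
| `n_folds` | 20 | — | cross-validation folds |
| `mmse_days` / `cdr_days` | 183 / 92 | days | six / three calendar months |

## Numerical choices

* **k-means** is Lloyd's algorithm with squared-Euclidean distance, run to
  the assignment fixpoint, best inertia over seeded random restarts.
  Assignment ties go to the lowest cluster index; empty clusters are
  re-seeded at the point farthest from its current centroid (ties to the
  lowest point index), keeping exactly k non-empty clusters
  deterministically. The default of 25 restarts was chosen after observing
  that 10 restarts can land the k = 4 fit in a visibly poor local optimum
  on realistic phantom instances (roughly double the optimal inertia, with
  two planted regions merged); 25 restarts found the better optimum on
  every instance examined, and the restart count remains configurable.
* **Cluster numbering** is canonical: descending across-subject mean SUVr
  of member voxels, ties by descending size, then lowest voxel index.
  Cluster 1 is therefore always the earliest/highest-burden territory and
  the numbering is stable across runs.
* **AUC** uses pooled out-of-fold decision scores via the midrank
  (Mann–Whitney) formula, equivalent to (concordant + ½·tied)/(n⁺·n⁻).
  With 20 folds, per-fold test sets are too small for stable per-fold
  AUCs; pooling is the documented convention. Confusion matrices are taken
  at the model's native boundary (SVM score 0, logistic probability 0.5).
* **Standardisation** to zero mean/unit SD is fitted on each training
  split only — voxel counts and SUVr live on scales three orders of
  magnitude apart, and leaking test statistics into the scaler would bias
  the cross-validation.
* **Degenerate inputs** are reported, not silently repaired: empty masks
  after thresholding raise an error naming the thresholds; zero-variance
  vectors make skewness `NA` and Pearson correlation an error; confusion
  cells with zero denominators are `NA`, never 0.
* Masks are stored as unsigned 8-bit NIfTI and continuous maps as 32-bit
  float (interoperability with standard viewers); round-trips therefore
  preserve mask values exactly and continuous values to single precision.

## What the phantom emulates — and what it does not

The generator builds a 40×48×40 grid (4 mm isotropic) containing a GM
shell, a WM core with constant elevated non-specific binding, a cerebellar
reference sphere at baseline, a broad composite cortical band, and four
disjoint ellipsoidal deposition regions. Its defaults are the package's
reference study conditions: 50 subjects per group, baseline SUVr 1.0 with
voxel noise SD 0.05, deposited voxels at +0.5 SUVr.

Deposition follows a **participation mixture**. For subject s and region
r, the subject deposits the region with its group's occupancy probability
(region 1: 0.50/0.65/0.80/0.95 for CN/EMCI/LMCI/AD … region 4:
0.05/0.10/—/0.80); a depositing subject covers the region centre-outwards
to a target extent of 0.90 ± 0.04 of its voxels with a fuzzy boundary. In
the designated bimodal region, LMCI subjects follow the AD model with
probability 0.5 and the CN model otherwise — which is the same mechanism,
and is what produces the two-peaked LMCI distribution in the late
cluster. Group-level occupancy therefore grows with stage (territory
"expands" across the cohort) while amyloid positivity remains bimodal
across individuals, as it is in real populations. A design alternative —
grading the per-subject spatial extent continuously by group — was
rejected: voxel profiles would then depend only on depth within a region,
k-means would recover depth bands cutting across regions, and no spatial
model could map clusters onto anatomy.

Two further realism terms matter for the classifier comparison. A
per-subject GM-wide offset (SD 0.04 SUVr) emulates between-subject
variability in non-specific grey-matter binding, which reference-region
normalisation does not remove; it inflates the variance of global
intensity measures (composite SUVr, GM mean) exactly as in real data,
while leaving profile-space clustering untouched (a common shift of every
voxel profile). Stage-graded diffuse deposition (0.5 %–5.5 % of
extra-regional GM voxels) gives whole-GM measures diagnostic signal that
the four cluster masks cannot see, so the six-feature classifier gains
over the clusters-only classifier for the same reason it does on real
scans. Clinical scores are affine in total deposited voxels
(MMSE slope −0.004/voxel, CDR slope +0.0005/voxel, noise SD 1.5 MMSE
points), placing group score ranges in instrument-typical territory
(AD MMSE ≈ 20–26, CN CDR ≈ 0–0.5).

The phantom does **not** emulate PET physics (Poisson noise, point-spread,
partial-volume effects), scanner harmonisation, registration error,
atrophy, or longitudinal trajectories. Passing tests on the phantom
therefore demonstrate that the pipeline's *computations* behave as
specified under controlled spatial structure — not that the classifier's
phantom operating point (accuracy ≈ 0.87–0.95) transfers to any real
cohort.

## Problem sizes used by the tests

The test suite runs the full pipeline twice on the default phantom (200
subjects, ~1300 mask voxels, k = 2…13) to check end-to-end behaviour and
byte-level determinism, and exercises the numerical oracles on small
instances: exhaustive k-means enumeration on 20 random instances of 6–14
voxels, brute-force AUC pair counting on 100 random score sets of up to 50
subjects, and flood-fill component labelling on 9³ grids. These sizes were
chosen so the oracles stay exact (enumeration over k^n assignments) while
the phantom remains large enough for the stochastic invariants to be
stable at a fixed seed.

## Known limitations

* Inputs must already be co-registered to one grid; mixed grids are
  refused rather than resampled, and no registration, segmentation or
  partial-volume correction is provided.
* The feature table is defined for the k = 4 model; other k values are
  fitted, exported and silhouette-scored but not fed to the classifier.
* SVM hyperparameters (cost, kernel coefficient) are exposed but not
  tuned; the comparison is between feature sets, not over a hyperparameter
  search.
* Pearson associations are unadjusted for age, sex or multiple
  comparisons, matching the descriptive intent of the association tables.
* With 20 folds on small cohorts a test fold may contain one class; pooled
  metrics remain defined, but per-fold metrics would not — another reason
  pooling is the convention.
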