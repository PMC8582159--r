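# abclust — data-driven spatial classification of amyloid-β PET

`abclust` implements a spatially informed, data-driven pipeline for
classifying amyloid-β PET scans along the Alzheimer's disease (AD)
continuum. It is aimed at neuroimaging researchers who have per-subject
SUVr (standardised uptake value ratio) volumes co-registered to one
template grid, together with grey-matter (GM), white-matter (WM),
cerebellar-reference and composite-cortical-ROI masks, and want to go
beyond the conventional composite SUVr read-out by exploiting *where*
amyloid accumulates and how amyloid-positive clusters *expand* with
disease stage.

## The method

Starting from a cohort of SUVr volumes with diagnostic labels
(CN / EMCI / LMCI / AD):

1. **SUVr quantification.** Each volume is normalised by its mean over the
   cerebellar GM reference region: `SUVr(v) = SUV(v) / mean(SUV | reference)`.
2. **Group maps and the AD-variance mask.** Voxel-wise group mean and SD
   images are computed on the GM mask, and each clinical group is compared
   with controls through `z(v) = (mean_g(v) − mean_CN(v)) / sd_CN(v)`. The
   analysis mask keeps voxels where the AD-group mean SUVr reaches the
   conventional positivity cut-point (1.1) **and** the AD z-score is
   positive, then drops connected components smaller than 10 voxels
   (de-noising). This focuses all later stages on the voxels where amyloid
   varies most in AD.
3. **Voxel clustering.** Within that mask, each voxel is represented by its
   across-subject SUVr profile and the voxels are partitioned by seeded
   k-means (Lloyd's algorithm, squared-Euclidean distance, best of 25
   restarts) for every k from 2 to 13. Every cluster division is exported
   as a binary mask — 90 masks over the default range — and silhouette
   diagnostics are reported per k. Clusters are renumbered canonically by
   descending mean SUVr, so cluster 1 is always the highest-burden
   (earliest) territory and cluster 4 the latest.
4. **Feature extraction.** For every subject: amyloid-positive voxel counts
   (SUVr > 1.1) inside clusters 1–4 and inside the whole GM mask, the GM
   mean SUVr, the composite-ROI SUVr (the conventional global measure) and
   the WM mean SUVr (a spillover control).
5. **Classification.** AD vs CN with a quadratic-kernel SVM on the six
   features (cluster 1–4 counts, GM positive count, GM mean SUVr) under
   stratified 20-fold cross-validation, compared against the clusters-only
   SVM, a composite-SUVr-only logistic model and a two-feature GM logistic
   model — all on shared folds. Sensitivity, specificity, accuracy,
   AUC-ROC (from pooled out-of-fold scores) and error rate are tabulated.
6. **Clinical associations.** MMSE/CDR scores are matched to scans within
   183/92-day windows; per-cluster, per-group medians, IQRs and skewness
   g1 = m3/m2^(3/2) are tabulated, plus Pearson correlations of cluster
   counts with MMSE and CDR.

Because real amyloid PET cohorts are access-controlled, the package ships a
fully synthetic **phantom cohort generator**: ellipsoidal GM/WM/cerebellar
geometry with four planted deposition regions whose per-group occupancy
expands with clinical stage, a bimodal late region in LMCI, diffuse
non-focal deposition, and MMSE/CDR scores coupled to deposition burden.
Every stage of the pipeline is exercised and tested against this phantom.

## Worked example

Run the full pipeline on the default phantom (200 subjects, 40×48×40 grid,
4 mm voxels) from R:

```r
library(abclust)
run_pipeline(list(out_dir = "abclust_out", seed = 42))
```

or from the shell via the bundled executable:

```sh
abclust run --out-dir abclust_out --seed 42
```

This writes the phantom cohort, group mean/SD/z maps, `maps/ad_mask.nii.gz`
(1307 voxels at the default thresholds), 90 division masks under
`clusters/divisions/`, per-subject features, and the classification and
association tables. The classifier comparison
(`classification/metrics.tsv`) reads:

```
         method features sensitivity specificity accuracy    auc error_rate
   six_features        6        0.88        0.86     0.87 0.9528       0.13
   clusters_1_4        4        0.86        0.86     0.86 0.9464       0.14
 composite_suvr        1        0.70        0.68     0.69 0.7628       0.31
         gm_two        2        0.68        0.60     0.64 0.7216       0.36
```

The spatially informed six-feature SVM dominates: adding the four cluster
counts recovers the region-confined signal that the global composite SUVr
dilutes, and the GM features contribute the diffuse component the clusters
miss. The clinical associations
(`associations/clinical_correlations.tsv`) show every cluster's positive
count correlating negatively with MMSE and positively with CDR, strongest
for the late cluster 4 (r = −0.68 with MMSE, +0.62 with CDR), and the
cluster-4 distribution table reproduces the hallmark staging pattern: CN
skewed towards zero (g1 = +3.5), AD skewed towards full involvement
(g1 = −1.9), LMCI flat/bimodal in between (g1 ≈ 0).

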