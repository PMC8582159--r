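#' Amyloid positivity rule
#'
#' @param threshold SUVr cut-point; a voxel is amyloid-positive when its
#'   SUVr strictly exceeds it (default 1.1, the conventional florbetapir
#'   positivity threshold).
#' @return A `positivity_rule` list.
#' @export
positivity_rule <- function(threshold = 1.1) {
  if (threshold <= 0) stop("positivity threshold must be > 0")
  structure(list(threshold = threshold), class = "positivity_rule")
}

#' Count amyloid-positive voxels within a mask
#'
#' @param scan SUVr [pet_volume()].
#' @param mask [pet_mask()] on the same grid.
#' @param rule a [positivity_rule()].
#' @return Integer count of in-mask voxels with SUVr above the threshold.
#' @export
count_positive_voxels <- function(scan, mask, rule = positivity_rule()) {
  stopifnot(inherits(scan, "pet_volume"), inherits(mask, "pet_mask"),
            inherits(rule, "positivity_rule"))
  check_same_grid(scan, mask)
  sum(scan$values[mask$values == 1L] > rule$threshold)
}

#' Mean SUVr within a mask
#'
#' @param scan SUVr [pet_volume()].
#' @param mask non-empty [pet_mask()] on the same grid.
#' @return Arithmetic mean of the scan over the mask voxels.
#' @export
mean_suvr_in_mask <- function(scan, mask) {
  stopifnot(inherits(scan, "pet_volume"), inherits(mask, "pet_mask"))
  check_same_grid(scan, mask)
  if (voxel_count(mask) == 0L) stop("empty mask")
  mean(scan$values[mask$values == 1L])
}

#' Build the per-subject feature table
#'
#' For every subject in the manifest computes the eight per-subject
#' measures: amyloid-positive voxel counts in each of the four cluster
#' divisions (`cluster1_pos` .. `cluster4_pos`), the grey-matter positive
#' count (`gm_pos`), the grey-matter mean SUVr (`gm_mean_suvr`), the
#' composite cortical ROI mean SUVr (`composite_suvr`, the conventional
#' global burden measure) and the white-matter mean SUVr (`wm_mean_suvr`,
#' the spillover check). The first six are the classifier features.
#'
#' @param manifest cohort manifest (see [read_manifest()]).
#' @param cluster_masks list of four pairwise-disjoint [pet_mask()] cluster
#'   divisions (canonical order: cluster 1 = highest burden).
#' @param gm,composite,wm grey-matter, composite-ROI and white-matter masks.
#' @param rule a [positivity_rule()].
#' @param reference_mask optional reference mask; when given, scans are
#'   SUVr-normalised with [compute_suvr()] before measurement.
#' @return Data frame with one row per subject, ordered by `subject_id`.
#' @export
build_feature_table <- function(manifest, cluster_masks, gm, composite, wm,
                                rule = positivity_rule(),
                                reference_mask = NULL) {
  if (length(cluster_masks) != 4L)
    stop("expected 4 cluster division masks, got ", length(cluster_masks))
  for (i in seq_along(cluster_masks)) {
    stopifnot(inherits(cluster_masks[[i]], "pet_mask"))
    for (j in seq_len(i - 1L)) {
      if (voxel_count(mask_intersect(cluster_masks[[i]], cluster_masks[[j]])) > 0L)
        stop("cluster masks ", j, " and ", i, " overlap; divisions must be disjoint")
    }
  }
  paths <- manifest_scan_paths(manifest)
  ord <- order(manifest$subject_id)
  rows <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    s <- ord[r]
    scan <- read_volume(paths[s], expected_grid = dim(gm$values))
    if (!is.null(reference_mask)) scan <- compute_suvr(scan, reference_mask)
    counts <- vapply(cluster_masks, count_positive_voxels, 0L,
                     scan = scan, rule = rule)
    rows[[r]] <- data.frame(
      subject_id = manifest$subject_id[s], group = manifest$group[s],
      cluster1_pos = counts[1L], cluster2_pos = counts[2L],
      cluster3_pos = counts[3L], cluster4_pos = counts[4L],
      gm_pos = count_positive_voxels(scan, gm, rule),
      gm_mean_suvr = mean_suvr_in_mask(scan, gm),
      composite_suvr = mean_suvr_in_mask(scan, composite),
      wm_mean_suvr = mean_suvr_in_mask(scan, wm),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature column sets of the compared classifiers
#'
#' @param feature_set one of `"six_features"` (the four cluster counts plus
#'   the two grey-matter measures), `"clusters_1_4"`, `"composite_suvr"`,
#'   `"gm_two"`.
#' @return Character vector of feature-table column names.
#' @export
feature_columns <- function(feature_set) {
  switch(match.arg(feature_set,
                   c("six_features", "clusters_1_4", "composite_suvr", "gm_two")),
         six_features = c("cluster1_pos", "cluster2_pos", "cluster3_pos",
                          "cluster4_pos", "gm_pos", "gm_mean_suvr"),
         clusters_1_4 = c("cluster1_pos", "cluster2_pos", "cluster3_pos",
                          "cluster4_pos"),
         composite_suvr = "composite_suvr",
         gm_two = c("gm_pos", "gm_mean_suvr"))
}
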