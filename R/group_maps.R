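#' Quantify SUVr by reference-region normalisation
#'
#' Divides a (SUV or SUVr) volume by its mean value over the reference
#' region (cerebellar grey matter in the standard amyloid PET workflow),
#' yielding a standardised uptake value ratio image. The operation is
#' scale-invariant, so applying it to an already-normalised image is a
#' no-op up to the reference-region noise.
#'
#' @param suv a [pet_volume()].
#' @param reference_mask non-empty [pet_mask()] on the same grid.
#' @return A [pet_volume()] of SUVr values.
#' @export
compute_suvr <- function(suv, reference_mask) {
  stopifnot(inherits(suv, "pet_volume"), inherits(reference_mask, "pet_mask"))
  check_same_grid(suv, reference_mask)
  if (voxel_count(reference_mask) == 0L) stop("empty reference mask")
  ref_mean <- mean(suv$values[reference_mask$values == 1L])
  if (ref_mean <= 0) stop("non-positive reference-region mean: ", ref_mean)
  pet_volume(suv$values / ref_mean, suv$affine, suv$space)
}

#' Voxel-wise group mean and SD maps
#'
#' Computes the voxel-wise arithmetic mean and sample standard deviation
#' (n - 1 denominator) across a group's SUVr volumes, restricted to the
#' grey-matter mask; voxels outside the mask are 0.
#'
#' @param volumes list of at least two [pet_volume()] objects on one grid.
#' @param gm_mask grey-matter [pet_mask()].
#' @param group optional group label carried in the result.
#' @return A `group_stat_maps` list with `mean_map`, `sd_map` (both
#'   [pet_volume()]), `mask`, `group` and `n`.
#' @export
group_mean_sd <- function(volumes, gm_mask, group = NA_character_) {
  if (length(volumes) < 2L) stop("need at least 2 volumes for mean/SD maps")
  stopifnot(inherits(gm_mask, "pet_mask"))
  for (v in volumes) check_same_grid(v, gm_mask)
  n <- length(volumes)
  sum1 <- array(0, dim = dim(gm_mask$values))
  sum2 <- array(0, dim = dim(gm_mask$values))
  for (v in volumes) {
    sum1 <- sum1 + v$values
    sum2 <- sum2 + v$values^2
  }
  m <- sum1 / n
  # sample variance with n-1 denominator; guard tiny negatives from rounding
  va <- pmax(sum2 - n * m^2, 0) / (n - 1)
  inmask <- gm_mask$values == 1L
  m[!inmask] <- 0
  va[!inmask] <- 0
  structure(list(group = group,
                 mean_map = pet_volume(m, gm_mask$affine, gm_mask$space),
                 sd_map = pet_volume(sqrt(va), gm_mask$affine, gm_mask$space),
                 mask = gm_mask, n = n),
            class = "group_stat_maps")
}

#' @export
print.group_stat_maps <- function(x, ...) {
  cat(sprintf("<group_stat_maps> group %s, n = %d, grid %s\n",
              x$group, x$n, paste(dim(x$mean_map$values), collapse = "x")))
  invisible(x)
}

#' Voxel-wise z-score map of a group against controls
#'
#' z = (group mean - CN mean) / CN SD at every voxel where the control SD is
#' positive; those voxels form the returned validity mask. Voxels with zero
#' control SD are excluded rather than clamped, avoiding infinite scores.
#'
#' @param group a `group_stat_maps` for the clinical group (EMCI/LMCI/AD).
#' @param cn the control-group `group_stat_maps`.
#' @return A `zscore_map` list: `group`, `z_map` ([pet_volume()]), and
#'   `valid_mask` ([pet_mask()]).
#' @export
zscore_map <- function(group, cn) {
  stopifnot(inherits(group, "group_stat_maps"), inherits(cn, "group_stat_maps"))
  check_same_grid(group$mean_map, cn$mean_map)
  valid <- cn$sd_map$values > 0 & cn$mask$values == 1L & group$mask$values == 1L
  z <- array(0, dim = dim(cn$mean_map$values))
  z[valid] <- (group$mean_map$values[valid] - cn$mean_map$values[valid]) /
    cn$sd_map$values[valid]
  structure(list(group = group$group,
                 z_map = pet_volume(z, cn$mean_map$affine, cn$mean_map$space),
                 valid_mask = pet_mask(valid, cn$mean_map$affine, cn$mean_map$space)),
            class = "zscore_map")
}

#' AD-variance mask specification
#'
#' @param suvr_threshold AD-group mean SUVr must reach this value
#'   (default 1.1, the conventional amyloid positivity cut-point).
#' @param z_threshold AD z-score must exceed this value (default 0). Setting
#'   either threshold to its floor degenerates to a single-criterion mask.
#' @param min_component_voxels smallest connected component kept by
#'   de-noising.
#' @param connectivity component connectivity (6, 18 or 26).
#' @return An `ad_mask_spec` list.
#' @export
ad_mask_spec <- function(suvr_threshold = 1.1, z_threshold = 0,
                         min_component_voxels = 10L, connectivity = 6L) {
  if (suvr_threshold <= 0) stop("suvr_threshold must be > 0")
  if (z_threshold < 0) stop("z_threshold must be >= 0")
  if (min_component_voxels < 1L) stop("min_component_voxels must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(suvr_threshold = suvr_threshold, z_threshold = z_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = as.integer(connectivity)),
            class = "ad_mask_spec")
}

#' Build the de-noised binarised AD-variance mask
#'
#' Selects voxels where the AD-group mean SUVr reaches `suvr_threshold` AND
#' the AD z-score against controls exceeds `z_threshold` (within the z-map's
#' validity mask), then removes connected components smaller than
#' `min_component_voxels`. The result focuses all downstream clustering on
#' the voxels where amyloid varies most in AD.
#'
#' @param ad_stats AD-group `group_stat_maps`.
#' @param ad_z AD `zscore_map` against CN.
#' @param spec an [ad_mask_spec()].
#' @return A [pet_mask()] with attribute `"spec"` recording the thresholds.
#' @export
build_ad_mask <- function(ad_stats, ad_z, spec = ad_mask_spec()) {
  stopifnot(inherits(ad_stats, "group_stat_maps"), inherits(ad_z, "zscore_map"),
            inherits(spec, "ad_mask_spec"))
  check_same_grid(ad_stats$mean_map, ad_z$z_map)
  raw <- ad_stats$mean_map$values >= spec$suvr_threshold &
    ad_z$z_map$values > spec$z_threshold &
    ad_z$valid_mask$values == 1L
  if (!any(raw))
    stop("AD mask is empty: no voxel satisfies mean SUVr >= ",
         spec$suvr_threshold, " and z > ", spec$z_threshold,
         " (thresholds likely mis-set)")
  m <- pet_mask(raw, ad_stats$mean_map$affine, ad_stats$mean_map$space)
  m <- remove_small_components(m, spec$min_component_voxels, spec$connectivity)
  if (voxel_count(m) == 0L)
    stop("AD mask is empty after component de-noising")
  attr(m, "spec") <- spec
  m
}

#' Build all group maps and the AD mask from a cohort manifest
#'
#' Convenience wrapper over the map-building stage: loads every scan,
#' normalises it to SUVr against the reference region, computes per-group
#' mean/SD maps, z-score maps for EMCI/LMCI/AD versus CN, and the de-noised
#' AD-variance mask.
#'
#' @param manifest cohort manifest (see [read_manifest()]).
#' @param gm_mask,reference_mask grey-matter and reference-region masks.
#' @param spec an [ad_mask_spec()].
#' @return List with `group_stats` (per group), `z_maps` (per non-CN group)
#'   and `ad_mask`.
#' @export
build_group_maps <- function(manifest, gm_mask, reference_mask,
                             spec = ad_mask_spec()) {
  paths <- manifest_scan_paths(manifest)
  groups <- c("CN", "EMCI", "LMCI", "AD")
  stats <- list()
  for (g in intersect(groups, unique(manifest$group))) {
    sel <- which(manifest$group == g)
    vols <- lapply(paths[sel], function(p) {
      compute_suvr(read_volume(p, expected_grid = dim(gm_mask$values)),
                   reference_mask)
    })
    vols <- lapply(vols, function(v) {
      v$values[gm_mask$values == 0L] <- 0
      v
    })
    stats[[g]] <- group_mean_sd(vols, gm_mask, group = g)
  }
  if (is.null(stats$CN)) stop("manifest contains no CN subjects; z-scores need controls")
  zmaps <- lapply(stats[setdiff(names(stats), "CN")],
                  function(gs) zscore_map(gs, stats$CN))
  ad_mask <- NULL
  if (!is.null(stats$AD))
    ad_mask <- build_ad_mask(stats$AD, zmaps$AD, spec)
  list(group_stats = stats, z_maps = zmaps, ad_mask = ad_mask)
}
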