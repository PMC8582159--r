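#' Define a deposition region for the phantom cohort
#'
#' A region is an ellipsoidal patch of grey matter in which amyloid
#' deposition is planted. Group differences are expressed through
#' `occupancy`: the expected fraction of the region's voxels deposited by an
#' average subject of each group. Deposition in an individual follows a
#' participation mixture (see [generate_cohort()]): a subject either carries
#' deposition in the region — growing from the region centre out to a target
#' extent — or does not, so group occupancy rises with clinical stage by
#' recruiting more depositing subjects, mirroring the bimodal nature of
#' amyloid positivity.
#'
#' @param name region identifier (unique within a config).
#' @param center voxel coordinate triple of the region centre.
#' @param radii ellipsoid semi-axes in voxels.
#' @param occupancy named vector (`CN`, `EMCI`, `LMCI`, `AD`) of expected
#'   occupancy fractions in `[0, 1]`.
#' @param added_suvr SUVr added to deposited voxels; scalar or named
#'   per-group vector.
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(name, center, radii, occupancy, added_suvr = 0.5) {
  groups <- c("CN", "EMCI", "LMCI", "AD")
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  occupancy <- occupancy[groups]
  if (anyNA(occupancy) || any(occupancy < 0 | occupancy > 1))
    stop("region '", name, "': occupancy must name CN/EMCI/LMCI/AD values in [0,1]")
  if (length(added_suvr) == 1L) added_suvr <- stats::setNames(rep(added_suvr, 4L), groups)
  added_suvr <- added_suvr[groups]
  if (anyNA(added_suvr) || any(added_suvr < 0))
    stop("region '", name, "': added_suvr must be >= 0")
  structure(list(name = name, center = as.numeric(center),
                 radii = as.numeric(radii), occupancy = occupancy,
                 added_suvr = added_suvr),
            class = "phantom_region")
}

#' Default planted regions of the phantom brain
#'
#' Four disjoint grey-matter regions with stage-graded occupancy: region 1
#' is deposited early (most cognitively normal subjects already carry it),
#' regions 2 and 3 are recruited progressively with disease stage, and
#' region 4 is a late region that separates late-MCI subjects into an
#' AD-like and a CN-like mode. Occupancy is non-decreasing along
#' CN -> EMCI -> LMCI -> AD in every region.
#'
#' @return List of four [phantom_region()] objects.
#' @export
default_phantom_regions <- function() {
  list(
    phantom_region("region1", center = c(20.5, 38.0, 26.0), radii = c(6, 5, 4),
                   occupancy = c(CN = 0.50, EMCI = 0.65, LMCI = 0.80, AD = 0.95)),
    phantom_region("region2", center = c(11.0, 30.0, 24.0), radii = c(4, 4, 4),
                   occupancy = c(CN = 0.30, EMCI = 0.45, LMCI = 0.60, AD = 0.75)),
    phantom_region("region3", center = c(30.0, 30.0, 24.0), radii = c(5, 4, 4),
                   occupancy = c(CN = 0.10, EMCI = 0.25, LMCI = 0.45, AD = 0.65)),
    phantom_region("region4", center = c(20.5, 12.5, 28.0), radii = c(4, 4, 5),
                   occupancy = c(CN = 0.05, EMCI = 0.10, LMCI = 0.42, AD = 0.80))
  )
}

#' Configure the synthetic phantom cohort
#'
#' @param grid integer shape triple of the template grid.
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param n_per_group named counts of subjects per diagnostic group.
#' @param baseline_suvr SUVr of non-deposited grey matter (reference region
#'   sits at this level, so generated images are SUVr-scaled).
#' @param baseline_noise_sd voxel-wise Gaussian noise SD.
#' @param gm_offset_sd SD of a per-subject additive offset applied to all
#'   grey-matter voxels, emulating between-subject variability in
#'   non-specific grey-matter tracer binding (grey-white differentiation
#'   varies between individuals independently of amyloid load, and is not
#'   removed by reference-region normalisation).
#' @param wm_suvr white-matter SUVr, identical across groups (non-specific
#'   white-matter binding carries no diagnostic signal).
#' @param diffuse_fraction named per-group expected fraction of grey-matter
#'   voxels outside the planted regions carrying scattered low-level
#'   deposition (amyloid is not confined to focal clusters; this diffuse
#'   component is visible to whole-grey-matter measures but not to the
#'   cluster divisions).
#' @param diffuse_subject_sd between-subject SD of the diffuse fraction.
#' @param regions list of [phantom_region()] objects; pairwise disjoint.
#' @param bimodal_region name of the region in which LMCI subjects follow a
#'   two-mode (AD-like / CN-like) deposition mixture.
#' @param lmci_bimodal_fraction fraction of LMCI subjects drawn from the AD
#'   deposition model in the bimodal region.
#' @param extent_mean,extent_sd target spatial extent (fraction of the
#'   region covered, centre outwards) of a depositing subject, and its
#'   between-subject SD.
#' @param edge_jitter per-voxel SD (in extent fraction units) of the
#'   deposition boundary, making region edges fuzzy.
#' @param mmse_slope change in MMSE per deposited voxel (negative).
#' @param cdr_slope change in CDR per deposited voxel (positive).
#' @param score_noise_sd noise SD of the MMSE score (CDR uses a tenth of it,
#'   matching the scales of the two instruments).
#' @param seed integer seed; a fixed seed makes the cohort fully
#'   reproducible.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid = c(40L, 48L, 40L),
                           voxel_mm = 4,
                           n_per_group = c(CN = 50L, EMCI = 50L, LMCI = 50L, AD = 50L),
                           baseline_suvr = 1.0,
                           baseline_noise_sd = 0.05,
                           gm_offset_sd = 0.04,
                           wm_suvr = 1.35,
                           diffuse_fraction = c(CN = 0.005, EMCI = 0.015,
                                                LMCI = 0.03, AD = 0.055),
                           diffuse_subject_sd = 0.01,
                           regions = default_phantom_regions(),
                           bimodal_region = "region4",
                           lmci_bimodal_fraction = 0.5,
                           extent_mean = 0.9,
                           extent_sd = 0.04,
                           edge_jitter = 0.02,
                           mmse_slope = -0.004,
                           cdr_slope = 5e-4,
                           score_noise_sd = 1.5,
                           seed = 42L) {
  groups <- c("CN", "EMCI", "LMCI", "AD")
  n_per_group <- n_per_group[groups]
  if (anyNA(n_per_group) || any(n_per_group < 0))
    stop("n_per_group must name non-negative CN/EMCI/LMCI/AD counts")
  if (sum(n_per_group) == 0L) stop("empty cohort: all group sizes are zero")
  stopifnot(length(grid) == 3L, all(grid > 0), voxel_mm > 0,
            baseline_suvr > 0, baseline_noise_sd >= 0, gm_offset_sd >= 0,
            lmci_bimodal_fraction >= 0, lmci_bimodal_fraction <= 1,
            extent_mean > 0, extent_mean <= 1, extent_sd >= 0, edge_jitter >= 0,
            score_noise_sd >= 0)
  diffuse_fraction <- diffuse_fraction[groups]
  if (anyNA(diffuse_fraction) || any(diffuse_fraction < 0 | diffuse_fraction > 1))
    stop("diffuse_fraction must name CN/EMCI/LMCI/AD values in [0,1]")
  if (diffuse_subject_sd < 0) stop("diffuse_subject_sd must be >= 0")
  if (mmse_slope >= 0) stop("mmse_slope must be negative (cognition declines with deposition)")
  if (cdr_slope <= 0) stop("cdr_slope must be positive")
  if (!all(vapply(regions, inherits, TRUE, "phantom_region")))
    stop("regions must be phantom_region objects")
  nm <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("region names must be unique")
  if (!bimodal_region %in% nm) stop("bimodal_region '", bimodal_region, "' not among regions")
  structure(list(grid = as.integer(grid), voxel_mm = voxel_mm,
                 n_per_group = n_per_group, baseline_suvr = baseline_suvr,
                 baseline_noise_sd = baseline_noise_sd,
                 gm_offset_sd = gm_offset_sd, wm_suvr = wm_suvr,
                 diffuse_fraction = diffuse_fraction,
                 diffuse_subject_sd = diffuse_subject_sd,
                 regions = regions, bimodal_region = bimodal_region,
                 lmci_bimodal_fraction = lmci_bimodal_fraction,
                 extent_mean = extent_mean, extent_sd = extent_sd,
                 edge_jitter = edge_jitter, mmse_slope = mmse_slope,
                 cdr_slope = cdr_slope, score_noise_sd = score_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_affine <- function(config) {
  aff <- diag(c(rep(config$voxel_mm, 3L), 1))
  aff[1:3, 4L] <- -config$voxel_mm * (config$grid / 2)
  aff
}

phantom_space <- function(config) {
  sprintf("phantom-%s", paste(config$grid, collapse = "x"))
}

# Squared ellipsoidal radius of every grid voxel around 'center'
ellipsoid_u2 <- function(grid, center, radii) {
  x <- (seq_len(grid[1L]) - center[1L]) / radii[1L]
  y <- (seq_len(grid[2L]) - center[2L]) / radii[2L]
  z <- (seq_len(grid[3L]) - center[3L]) / radii[3L]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# Brain geometry shared by all subjects: GM shell, WM core, cerebellar
# reference sphere, composite cortical band, planted-region voxel lists.
phantom_geometry <- function(config) {
  g <- config$grid
  ctr <- (g + 1) / 2
  outer_u <- ellipsoid_u2(g, ctr, pmax(g * 0.42, 2))
  inner_u <- ellipsoid_u2(g, ctr, pmax(g * 0.21, 1))
  cereb_c <- c(ctr[1L], g[2L] * 0.17, g[3L] * 0.20)
  cereb_u <- ellipsoid_u2(g, cereb_c, rep(max(min(g) * 0.10, 1.5), 3L))
  cereb <- cereb_u <= 1
  wm <- inner_u <= 1 & !cereb
  gm <- outer_u <= 1 & inner_u > 1 & !cereb
  # composite cortical band: upper grey matter, containing all regions plus
  # a broad non-depositing margin (dilutes the composite SUVr signal the way
  # a standard large cortical composite does)
  zc <- slice.index(array(0, g), 3L)
  composite <- gm & zc >= round(g[3L] * 0.45)
  regions <- lapply(config$regions, function(r) {
    u2 <- ellipsoid_u2(g, r$center, r$radii)
    idx <- which(u2 <= 1 & gm)
    if (length(idx) == 0L) stop("region '", r$name, "' contains no grey-matter voxels")
    ord <- order(u2[idx], idx)         # centre-out, deterministic ties
    idx <- idx[ord]
    q <- (seq_along(idx) - 0.5) / length(idx)
    list(name = r$name, idx = idx, q = q,
         occupancy = r$occupancy, added_suvr = r$added_suvr)
  })
  all_idx <- unlist(lapply(regions, `[[`, "idx"))
  if (anyDuplicated(all_idx)) stop("overlapping regions: planted regions must be pairwise disjoint")
  list(gm = gm, wm = wm, cereb = cereb, composite = composite,
       regions = regions, nonregion_gm = setdiff(which(gm), all_idx),
       affine = phantom_affine(config), space = phantom_space(config))
}

#' Generate the synthetic phantom cohort
#'
#' Writes one SUVr NIfTI volume per subject plus the grey-matter,
#' white-matter, cerebellar-reference and composite-ROI masks, a planted
#' ground-truth region label map (synthetic truth, for validation only) and
#' a tab-separated cohort manifest with diagnostic groups and dated MMSE/CDR
#' scores.
#'
#' Per subject and region, deposition follows a participation mixture: the
#' subject deposits the region with the group's occupancy probability, and a
#' depositing subject covers the region centre-outwards up to a target
#' extent (`extent_mean` +/- `extent_sd`, fuzzy boundary per `edge_jitter`),
#' raising covered voxels by `added_suvr`. In the designated bimodal region,
#' LMCI subjects follow the AD deposition model with probability
#' `lmci_bimodal_fraction` and the CN model otherwise. MMSE decreases and
#' CDR increases affinely with the subject's total deposited voxel count
#' (plus noise); MMSE is clipped to 0-30, CDR snapped to
#' \{0, 0.5, 1, 2, 3\}. White matter takes a group-independent SUVr.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if needed).
#' @return The cohort manifest as a data frame (invisibly written to
#'   `manifest.tsv`); attribute `"dir"` holds `out_dir`, attribute `"truth"`
#'   per-subject planted deposition totals.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  geo <- phantom_geometry(config)
  aff <- geo$affine; space <- geo$space
  write_volume(pet_mask(geo$gm, aff, space), file.path(out_dir, "gm_mask.nii.gz"))
  write_volume(pet_mask(geo$wm, aff, space), file.path(out_dir, "wm_mask.nii.gz"))
  write_volume(pet_mask(geo$cereb, aff, space), file.path(out_dir, "reference_mask.nii.gz"))
  write_volume(pet_mask(geo$composite, aff, space), file.path(out_dir, "composite_mask.nii.gz"))
  # synthetic planted truth: modal deposition footprint of each region
  truth_lab <- array(0L, dim = config$grid)
  for (i in seq_along(geo$regions)) {
    r <- geo$regions[[i]]
    truth_lab[r$idx[r$q <= config$extent_mean]] <- i
  }
  truth_img <- pet_volume(truth_lab + 0, aff, space)
  write_volume(truth_img, file.path(out_dir, "planted_truth_synthetic.nii.gz"))

  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  rows <- vector("list", n)
  total_deposited <- numeric(n)
  withr::with_seed(config$seed, {
    scan_dates <- as.Date("2011-01-01") + sample.int(730L, n, replace = TRUE)
    for (s in seq_len(n)) {
      grp <- groups[s]
      vol <- array(0, dim = config$grid)
      vol[geo$gm] <- config$baseline_suvr +
        stats::rnorm(1, 0, config$gm_offset_sd)
      vol[geo$cereb] <- config$baseline_suvr
      vol[geo$wm] <- config$wm_suvr
      dep_total <- 0L
      for (r in geo$regions) {
        eff_grp <- grp
        if (grp == "LMCI" && r$name == config$bimodal_region)
          eff_grp <- if (stats::runif(1) < config$lmci_bimodal_fraction) "AD" else "CN"
        if (stats::runif(1) < r$occupancy[[eff_grp]]) {
          extent <- min(max(stats::rnorm(1, config$extent_mean, config$extent_sd), 0.5), 1)
          covered <- r$q + stats::rnorm(length(r$q), 0, config$edge_jitter) <= extent
          vol[r$idx[covered]] <- vol[r$idx[covered]] + r$added_suvr[[grp]]
          dep_total <- dep_total + sum(covered)
        }
      }
      diff_frac <- min(max(stats::rnorm(1, config$diffuse_fraction[[grp]],
                                        config$diffuse_subject_sd), 0), 1)
      n_diff <- round(diff_frac * length(geo$nonregion_gm))
      if (n_diff > 0L) {
        dv <- sample(geo$nonregion_gm, n_diff)
        add <- mean(vapply(geo$regions, function(r) r$added_suvr[[grp]], 0))
        vol[dv] <- vol[dv] + add
        dep_total <- dep_total + n_diff
      }
      if (config$baseline_noise_sd > 0) {
        brain <- geo$gm | geo$wm | geo$cereb
        vol[brain] <- vol[brain] + stats::rnorm(sum(brain), 0, config$baseline_noise_sd)
        vol[brain] <- pmax(vol[brain], 0)
      }
      total_deposited[s] <- dep_total
      scan_file <- sprintf("%s_suvr.nii.gz", ids[s])
      write_volume(pet_volume(vol, aff, space), file.path(out_dir, scan_file))
      mmse <- round(29 + config$mmse_slope * dep_total +
                      stats::rnorm(1, 0, config$score_noise_sd))
      mmse <- as.integer(min(max(mmse, 0), 30))
      cdr_raw <- config$cdr_slope * dep_total +
        stats::rnorm(1, 0, 0.1 * config$score_noise_sd)
      cdr_levels <- c(0, 0.5, 1, 2, 3)
      cdr <- cdr_levels[which.min(abs(cdr_levels - cdr_raw))]
      rows[[s]] <- data.frame(
        subject_id = ids[s], group = grp, scan_path = scan_file,
        scan_date = format(scan_dates[s]),
        mmse = mmse,
        mmse_date = format(scan_dates[s] + round(stats::runif(1, -200, 200))),
        cdr = cdr,
        cdr_date = format(scan_dates[s] + round(stats::runif(1, -100, 100))),
        stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  truth <- data.frame(subject_id = ids, group = groups,
                      total_deposited = total_deposited,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(out_dir, "planted_truth_synthetic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(space = space, grid = config$grid, seed = config$seed,
         n_per_group = as.list(config$n_per_group),
         region_names = vapply(geo$regions, `[[`, "", "name"),
         region_voxels = vapply(geo$regions, function(r) length(r$idx), 0L)),
    file.path(out_dir, "phantom_provenance.json"), auto_unbox = TRUE)
  attr(manifest, "dir") <- out_dir
  attr(manifest, "truth") <- truth
  invisible(manifest)
}

#' Write a cohort manifest
#' @param manifest manifest data frame.
#' @param path output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path path to a tab-separated manifest with columns `subject_id`,
#'   `group`, `scan_path`, `scan_date` and optional dated `mmse`/`cdr`.
#' @return Data frame with attribute `"dir"` set to the manifest's
#'   directory, against which relative `scan_path` entries are resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("subject_id", "group", "scan_path", "scan_date")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$subject_id)) stop("duplicate subject_id in manifest")
  bad <- setdiff(unique(m$group), c("CN", "EMCI", "LMCI", "AD"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

manifest_scan_paths <- function(manifest) {
  dir <- attr(manifest, "dir")
  p <- manifest$scan_path
  rel <- !grepl("^(/|[A-Za-z]:)", p)
  if (any(rel)) {
    if (is.null(dir)) stop("manifest has relative scan paths but no base directory")
    p[rel] <- file.path(dir, p[rel])
  }
  p
}

#' Summarise a cohort manifest
#'
#' Per-group subject counts and counts of subjects whose MMSE/CDR scores
#' fall within the configured windows around the scan date.
#'
#' @param manifest manifest data frame (see [read_manifest()]).
#' @param windows a [match_windows()] specification.
#' @return Data frame with one row per group: `n`, `n_mmse`, `n_cdr`.
#' @export
cohort_summary <- function(manifest, windows = match_windows()) {
  if (nrow(manifest) == 0L) stop("empty manifest")
  bad <- setdiff(unique(manifest$group), c("CN", "EMCI", "LMCI", "AD"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  matched <- match_scores(manifest, windows)
  groups <- c("CN", "EMCI", "LMCI", "AD")
  out <- data.frame(group = groups,
                    n = vapply(groups, function(g) sum(manifest$group == g), 0L),
                    n_mmse = vapply(groups, function(g)
                      sum(matched$group == g & !is.na(matched$mmse)), 0L),
                    n_cdr = vapply(groups, function(g)
                      sum(matched$group == g & !is.na(matched$cdr)), 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
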