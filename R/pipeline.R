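pipeline_defaults <- function() {
  list(
    out_dir = "abclust_out",
    seed = 42L,
    manifest = NULL,
    gm_mask = NULL, wm_mask = NULL, reference_mask = NULL, composite_mask = NULL,
    simulate = list(enabled = TRUE, n_per_group = 50L, grid = c(40L, 48L, 40L)),
    ad_mask = list(suvr_threshold = 1.1, z_threshold = 0,
                   min_component_voxels = 10L, connectivity = 6L),
    clustering = list(k_min = 2L, k_max = 13L, k_select = 4L, restarts = 25L,
                      max_iterations = 1000L, representation = "subject_profile"),
    positivity = list(threshold = 1.1),
    classify = list(n_folds = 20L),
    windows = list(mmse_days = 183L, cdr_days = 92L),
    log_level = "info")
}

check_config_keys <- function(cfg, defaults, path = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        !is.null(cfg[[nm]])) {
      if (!is.list(cfg[[nm]]))
        stop("config key '", path, nm, "' must be a mapping", call. = FALSE)
      check_config_keys(cfg[[nm]], defaults[[nm]], paste0(path, nm, "."))
    }
  }
}

merge_config <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[nm] <- defaults[nm]
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      cfg[[nm]] <- merge_config(cfg[[nm]], defaults[[nm]])
    }
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults,
#' type- and range-checks every field and rejects unknown keys.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  check_config_keys(config, defaults)
  cfg <- merge_config(config, defaults)
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(cfg$ad_mask$suvr_threshold > 0, "ad_mask.suvr_threshold must be > 0")
  chk(cfg$ad_mask$z_threshold >= 0, "ad_mask.z_threshold must be >= 0")
  chk(cfg$ad_mask$min_component_voxels >= 1, "ad_mask.min_component_voxels must be >= 1")
  chk(cfg$ad_mask$connectivity %in% c(6, 18, 26), "ad_mask.connectivity must be 6, 18 or 26")
  chk(cfg$clustering$k_min >= 1, "clustering.k_min must be >= 1")
  chk(cfg$clustering$k_max >= cfg$clustering$k_min, "clustering.k_max must be >= k_min")
  chk(cfg$clustering$k_select >= cfg$clustering$k_min &&
        cfg$clustering$k_select <= cfg$clustering$k_max,
      "clustering.k_select must lie in [k_min, k_max]")
  chk(cfg$clustering$restarts >= 1, "clustering.restarts must be >= 1")
  chk(cfg$clustering$max_iterations >= 1, "clustering.max_iterations must be >= 1")
  chk(cfg$clustering$representation %in% c("subject_profile", "voxel_mean"),
      "clustering.representation must be subject_profile or voxel_mean")
  chk(cfg$positivity$threshold > 0, "positivity.threshold must be > 0")
  chk(cfg$classify$n_folds >= 2, "classify.n_folds must be >= 2")
  chk(cfg$windows$mmse_days > 0, "windows.mmse_days must be > 0")
  chk(cfg$windows$cdr_days > 0, "windows.cdr_days must be > 0")
  if (!isTRUE(cfg$simulate$enabled)) {
    for (p in c("manifest", "gm_mask", "wm_mask", "reference_mask", "composite_mask"))
      chk(is.character(cfg[[p]]) && file.exists(cfg[[p]]),
          paste0("missing required input '", p, "' (set simulate.enabled or provide the path)"))
  }
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

# Per-stage seeds derived from the master seed by a counter scheme, so
# stages are independently reproducible; kept inside 32-bit integer range.
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1009 + stage_index * 9973) %% 2147483647)
}

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(sprintf("[abclust %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> build-masks -> cluster -> extract-features ->
#' classify -> associate on one output directory. Stages whose outputs
#' already exist are skipped unless `force`. All randomness derives from
#' the master seed through per-stage counters, so two runs with one
#' configuration produce identical tables.
#'
#' @param config a [validate_config()] result, a config file path, or a
#'   named list of overrides.
#' @param force rerun stages whose outputs already exist.
#' @return Invisibly, a provenance list (config, per-stage seeds, output
#'   files with MD5 checksums), also written to `provenance.json` in the
#'   output directory.
#' @export
run_pipeline <- function(config = list(), force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, outputs, fun) {
    if (!force && length(outputs) && all(file.exists(outputs))) {
      pipeline_log(cfg, "stage ", name, ": outputs exist, skipping")
      return(invisible(NULL))
    }
    pipeline_log(cfg, "stage ", name, " ...")
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    sim_dir <- file.path(out, "phantom")
    run_stage("simulate", file.path(sim_dir, "manifest.tsv"), function() {
      n <- cfg$simulate$n_per_group
      pc <- phantom_config(grid = cfg$simulate$grid,
                           n_per_group = c(CN = n, EMCI = n, LMCI = n, AD = n),
                           seed = stage_seed(cfg$seed, 1L))
      generate_cohort(pc, sim_dir)
    })
    cfg$manifest <- file.path(sim_dir, "manifest.tsv")
    cfg$gm_mask <- file.path(sim_dir, "gm_mask.nii.gz")
    cfg$wm_mask <- file.path(sim_dir, "wm_mask.nii.gz")
    cfg$reference_mask <- file.path(sim_dir, "reference_mask.nii.gz")
    cfg$composite_mask <- file.path(sim_dir, "composite_mask.nii.gz")
  }
  manifest <- read_manifest(cfg$manifest)
  gm <- read_volume(cfg$gm_mask, as_mask = TRUE)
  wm <- read_volume(cfg$wm_mask, expected_grid = dim(gm$values), as_mask = TRUE)
  refm <- read_volume(cfg$reference_mask, expected_grid = dim(gm$values), as_mask = TRUE)
  comp <- read_volume(cfg$composite_mask, expected_grid = dim(gm$values), as_mask = TRUE)

  # --- build-masks ----------------------------------------------------
  maps_dir <- file.path(out, "maps")
  ad_mask_path <- file.path(maps_dir, "ad_mask.nii.gz")
  run_stage("build-masks", ad_mask_path, function() {
    dir.create(maps_dir, showWarnings = FALSE)
    spec <- ad_mask_spec(cfg$ad_mask$suvr_threshold, cfg$ad_mask$z_threshold,
                         cfg$ad_mask$min_component_voxels, cfg$ad_mask$connectivity)
    maps <- build_group_maps(manifest, gm, refm, spec)
    for (g in names(maps$group_stats)) {
      write_volume(maps$group_stats[[g]]$mean_map,
                   file.path(maps_dir, sprintf("%s_mean.nii.gz", g)))
      write_volume(maps$group_stats[[g]]$sd_map,
                   file.path(maps_dir, sprintf("%s_sd.nii.gz", g)))
    }
    for (g in names(maps$z_maps))
      write_volume(maps$z_maps[[g]]$z_map,
                   file.path(maps_dir, sprintf("%s_z.nii.gz", g)))
    write_volume(maps$ad_mask, ad_mask_path)
    jsonlite::write_json(list(spec = unclass(spec),
                              ad_mask_voxels = voxel_count(maps$ad_mask),
                              n_per_group = lapply(maps$group_stats, `[[`, "n")),
                         file.path(maps_dir, "ad_mask_provenance.json"),
                         auto_unbox = TRUE)
  })
  ad_mask <- read_volume(ad_mask_path, expected_grid = dim(gm$values), as_mask = TRUE)

  # --- cluster --------------------------------------------------------
  clus_dir <- file.path(out, "clusters")
  silhouette_path <- file.path(clus_dir, "silhouette.tsv")
  k_range <- seq(cfg$clustering$k_min, cfg$clustering$k_max)
  div_dir <- file.path(clus_dir, "divisions")
  run_stage("cluster", silhouette_path, function() {
    dir.create(clus_dir, showWarnings = FALSE)
    cseed <- stage_seed(cfg$seed, 2L)
    mat <- assemble_voxel_matrix(manifest, ad_mask, reference_mask = refm)
    models <- fit_cluster_models(mat, k_range, seed = cseed,
                                 n_restarts = cfg$clustering$restarts,
                                 max_iterations = cfg$clustering$max_iterations,
                                 representation = cfg$clustering$representation)
    for (m in models)
      write_volume(cluster_label_map(m),
                   file.path(clus_dir, sprintf("labels_k%02d.nii.gz", m$k)))
    export_division_masks(models, div_dir)
    sil <- do.call(rbind, lapply(models, function(m) {
      rep <- silhouette_scores(m, mat, seed = cseed)
      data.frame(k = m$k, overall = rep$overall,
                 cluster = seq_len(m$k), cluster_mean = rep$per_cluster,
                 inertia = m$inertia)
    }))
    write_tsv(sil, silhouette_path)
    jsonlite::write_json(
      list(seed = cseed, k_range = k_range,
           restarts = cfg$clustering$restarts,
           representation = cfg$clustering$representation,
           n_voxels = length(mat$voxel_index),
           n_subjects = nrow(mat$values),
           inertia = stats::setNames(lapply(models, `[[`, "inertia"), names(models))),
      file.path(clus_dir, "cluster_provenance.json"), auto_unbox = TRUE)
  })

  # --- extract-features ----------------------------------------------
  features_path <- file.path(out, "features.tsv")
  ks <- cfg$clustering$k_select
  run_stage("extract-features", features_path, function() {
    cl_masks <- lapply(1:4, function(c)
      read_volume(file.path(div_dir, sprintf("k%02d_cluster%02d.nii.gz", ks, c)),
                  expected_grid = dim(gm$values), as_mask = TRUE))
    feats <- build_feature_table(manifest, cl_masks, gm, comp, wm,
                                 rule = positivity_rule(cfg$positivity$threshold),
                                 reference_mask = refm)
    write_tsv(feats, features_path)
  })
  features <- utils::read.table(features_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)

  # --- classify -------------------------------------------------------
  cls_dir <- file.path(out, "classification")
  metrics_path <- file.path(cls_dir, "metrics.tsv")
  run_stage("classify", metrics_path, function() {
    dir.create(cls_dir, showWarnings = FALSE)
    cmp <- compare_feature_sets(features,
                                default_method_specs(n_folds = cfg$classify$n_folds),
                                seed = stage_seed(cfg$seed, 3L))
    write_tsv(cmp$metrics, metrics_path)
    write_tsv(cmp$pct_change, file.path(cls_dir, "pct_change.tsv"))
    for (nm in names(cmp$roc))
      write_tsv(cmp$roc[[nm]], file.path(cls_dir, sprintf("roc_%s.tsv", nm)))
    jsonlite::write_json(lapply(cmp$reports, `[[`, "confusion"),
                         file.path(cls_dir, "confusion.json"), auto_unbox = TRUE)
  })

  # --- associate ------------------------------------------------------
  assoc_dir <- file.path(out, "associations")
  dist_path <- file.path(assoc_dir, "cluster_distributions.tsv")
  run_stage("associate", dist_path, function() {
    dir.create(assoc_dir, showWarnings = FALSE)
    win <- match_windows(cfg$windows$mmse_days, cfg$windows$cdr_days)
    write_tsv(group_distribution_summary(features), dist_path)
    write_tsv(clinical_correlations(features, manifest, win),
              file.path(assoc_dir, "clinical_correlations.tsv"))
    write_tsv(match_scores(manifest, win),
              file.path(assoc_dir, "matched_scores.tsv"))
  })

  # --- provenance -----------------------------------------------------
  outputs <- list.files(out, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out, "provenance.json"))
  prov <- list(package_version = as.character(utils::packageVersion("abclust")),
               r_version = R.version.string,
               config = unclass(cfg),
               stage_seeds = list(simulate = stage_seed(cfg$seed, 1L),
                                  cluster = stage_seed(cfg$seed, 2L),
                                  classify = stage_seed(cfg$seed, 3L)),
               outputs = lapply(stats::setNames(outputs, sub(paste0("^", out, "/?"), "", outputs)),
                                function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(prov, file.path(out, "provenance.json"), auto_unbox = TRUE)
  pipeline_log(cfg, "pipeline complete: ", out)
  invisible(prov)
}
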