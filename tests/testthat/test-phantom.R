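test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- phantom_config(n_per_group = c(CN = 2L, EMCI = 2L, LMCI = 2L, AD = 2L),
                        seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)
  attributes(m1)[c("dir", "truth")] <- NULL
  attributes(m2)[c("dir", "truth")] <- NULL
  expect_identical(m1, m2)
  for (f in c("manifest.tsv", "sub-001_suvr.nii.gz", "sub-008_suvr.nii.gz",
              "gm_mask.nii.gz", "planted_truth_synthetic.nii.gz"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
})

test_that("noise-free zero-occupancy phantom is flat at baseline inside GM", {
  regions <- lapply(default_phantom_regions(), function(r) {
    r$occupancy[] <- 0
    r
  })
  cfg <- phantom_config(n_per_group = c(CN = 1L, EMCI = 1L, LMCI = 1L, AD = 1L),
                        baseline_noise_sd = 0, gm_offset_sd = 0,
                        diffuse_fraction = c(CN = 0, EMCI = 0, LMCI = 0, AD = 0),
                        diffuse_subject_sd = 0,
                        regions = regions, seed = 1L)
  d <- withr::local_tempdir()
  man <- generate_cohort(cfg, d)
  gm <- read_volume(file.path(d, "gm_mask.nii.gz"), as_mask = TRUE)
  for (p in man$scan_path) {
    v <- read_volume(file.path(d, p))
    expect_equal(unique(as.vector(v$values[gm$values == 1L])), 1.0,
                 tolerance = 1e-6)
  }
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(n_per_group = c(CN = 0L, EMCI = 0L, LMCI = 0L, AD = 0L)),
               "empty cohort")
  expect_error(phantom_config(mmse_slope = 0.1), "negative")
  expect_error(phantom_config(cdr_slope = -1), "positive")
  expect_error(phantom_region("x", c(1, 1, 1), c(2, 2, 2),
                              occupancy = c(CN = 0.5, EMCI = 0.5, LMCI = 0.5, AD = 1.2)),
               "occupancy")
  overlapping <- list(
    phantom_region("a", c(20.5, 38, 26), c(5, 5, 4),
                   occupancy = c(CN = .1, EMCI = .2, LMCI = .3, AD = .4)),
    phantom_region("b", c(20.5, 37, 26), c(5, 5, 4),
                   occupancy = c(CN = .1, EMCI = .2, LMCI = .3, AD = .4)))
  cfg <- phantom_config(n_per_group = c(CN = 1L, EMCI = 0L, LMCI = 0L, AD = 1L),
                        regions = overlapping, bimodal_region = "a")
  expect_error(generate_cohort(cfg, withr::local_tempdir()), "overlap")
})

test_that("group deposition separates AD from CN and expands monotonically", {
  ph <- default_run_phantom()
  man <- read_manifest(file.path(ph, "manifest.tsv"))
  truth <- read_volume(file.path(ph, "planted_truth_synthetic.nii.gz"))
  cfg <- phantom_config()   # defaults = the generated conditions
  region_masks <- lapply(1:4, function(i)
    pet_mask(truth$values == i, truth$affine))
  paths <- manifest_scan_paths(man)
  counts <- matrix(0L, nrow(man), 4)
  r1_mean <- numeric(nrow(man))
  for (s in seq_len(nrow(man))) {
    v <- read_volume(paths[s])
    counts[s, ] <- vapply(region_masks, count_positive_voxels, 0L, scan = v)
    r1_mean[s] <- mean_suvr_in_mask(v, region_masks[[1]])
  }
  grp <- factor(man$group, c("CN", "EMCI", "LMCI", "AD"))

  # region-1 mean SUVr contrast exceeds 3 x voxel noise SD
  expect_gt(mean(r1_mean[grp == "AD"]) - mean(r1_mean[grp == "CN"]),
            3 * cfg$baseline_noise_sd)

  # expansion structure: every region's burden rises with clinical stage
  # (positive trend), and the mean positive count over the whole planted
  # territory is strictly non-decreasing CN -> EMCI -> LMCI -> AD
  for (r in 1:4)
    expect_gt(stats::cor(as.integer(grp), counts[, r]),
              0, label = sprintf("region %d stage trend", r))
  total <- rowSums(counts)
  expect_true(all(diff(tapply(total, grp, mean)) >= 0))

  # LMCI bimodality in the designated late region: a two-component split
  # separates the modes by far more than the within-mode spread
  x <- counts[grp == "LMCI", 4]
  km <- stats::kmeans(x, centers = range(x))
  lo <- x[km$cluster == which.min(km$centers)]
  hi <- x[km$cluster == which.max(km$centers)]
  within_sd <- sqrt(max(stats::var(lo), stats::var(hi)))
  expect_gt(abs(mean(hi) - mean(lo)), 4 * within_sd)

  # cognition tracks deposition: MMSE negatively, CDR positively
  tr <- utils::read.table(file.path(ph, "planted_truth_synthetic.tsv"),
                          header = TRUE, sep = "\t")
  tr <- tr[match(man$subject_id, tr$subject_id), ]
  expect_lt(stats::cor(tr$total_deposited, man$mmse), 0)
  expect_gt(stats::cor(tr$total_deposited, man$cdr), 0)
})

test_that("cohort summary counts subjects and windowed scores per group", {
  man <- data.frame(
    subject_id = sprintf("s%02d", 1:15),
    group = c(rep("CN", 10), rep("AD", 5)),
    scan_path = "x.nii.gz", scan_date = "2012-06-01",
    stringsAsFactors = FALSE)
  s <- cohort_summary(man)
  expect_identical(s$n, c(10L, 0L, 0L, 5L))
  expect_identical(s$n_mmse, rep(0L, 4))

  man$mmse <- 25L; man$mmse_date <- man$scan_date
  man$cdr <- 0.5; man$cdr_date <- man$scan_date
  s2 <- cohort_summary(man)
  expect_identical(s2$n_mmse, s2$n)
  expect_identical(s2$n_cdr, s2$n)

  # random offsets vs a brute-force date filter
  withr::with_seed(77, {
    off_m <- sample(-400:400, 15)
    off_c <- sample(-400:400, 15)
  })
  man$mmse_date <- format(as.Date(man$scan_date) + off_m)
  man$cdr_date <- format(as.Date(man$scan_date) + off_c)
  s3 <- cohort_summary(man, match_windows(183, 92))
  for (g in c("CN", "AD")) {
    sel <- man$group == g
    expect_identical(s3$n_mmse[s3$group == g], sum(abs(off_m[sel]) <= 183))
    expect_identical(s3$n_cdr[s3$group == g], sum(abs(off_c[sel]) <= 92))
  }
  expect_error(cohort_summary(transform(man, group = "MCI")), "unknown group")
})
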