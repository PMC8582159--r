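test_that("SUVr normalisation divides by the reference mean and is scale-invariant", {
  ref_vals <- array(0L, c(4, 4, 4)); ref_vals[1:2, 1, 1] <- 1L
  ref <- pet_mask(ref_vals, diag(4))

  expect_equal(compute_suvr(const_volume(2.0), ref)$values,
               array(1.0, c(4, 4, 4)))

  # voxel 1.8 against a reference region whose mean is 1.5 -> 1.2
  v <- const_volume(1.5)
  v$values[4, 4, 4] <- 1.8
  expect_equal(compute_suvr(v, ref)$values[4, 4, 4], 1.2)

  rv <- rand_volume(c(8, 8, 8), seed = 5)
  big_ref_vals <- array(0L, c(8, 8, 8)); big_ref_vals[1:10] <- 1L
  big_ref <- pet_mask(big_ref_vals, diag(4))
  got <- compute_suvr(rv, big_ref)
  # explicit mean-then-divide loop oracle
  ref_mean <- mean(rv$values[1:10])
  expected <- rv$values
  for (i in seq_along(expected)) expected[i] <- rv$values[i] / ref_mean
  expect_equal(got$values, expected)

  for (c in c(0.5, 3, 100)) {
    scaled <- pet_volume(rv$values * c, rv$affine)
    expect_equal(compute_suvr(scaled, big_ref)$values, got$values,
                 tolerance = 1e-12)
  }
  empty <- pet_mask(array(0L, c(8, 8, 8)), diag(4))
  expect_error(compute_suvr(rv, empty), "empty reference")
  zero <- const_volume(0, c(8, 8, 8))
  expect_error(compute_suvr(zero, big_ref), "non-positive")
})

test_that("group mean/SD maps match closed-form and per-voxel oracles", {
  gm <- pet_mask(array(1L, c(6, 6, 6)), diag(4))

  v <- rand_volume(c(6, 6, 6), seed = 6)
  same <- group_mean_sd(list(v, v), gm)
  expect_true(all(same$sd_map$values == 0))

  two <- group_mean_sd(list(const_volume(1, c(6, 6, 6)),
                            const_volume(2, c(6, 6, 6))), gm)
  expect_equal(two$mean_map$values, array(1.5, c(6, 6, 6)))
  expect_equal(two$sd_map$values, array(sqrt(0.5), c(6, 6, 6)),
               tolerance = 1e-12)   # |1-2|/sqrt(2) ~ 0.7071

  vols <- lapply(1:20, function(s) rand_volume(c(6, 6, 6), seed = 500 + s))
  gs <- group_mean_sd(vols, gm)
  stack <- sapply(vols, function(v) as.vector(v$values))
  expect_equal(as.vector(gs$mean_map$values), apply(stack, 1, mean))
  expect_equal(as.vector(gs$sd_map$values), apply(stack, 1, sd),
               tolerance = 1e-10)
  expect_error(group_mean_sd(vols[1], gm), "at least 2")

  # outside-mask voxels are zeroed
  half <- array(0L, c(6, 6, 6)); half[1:3, , ] <- 1L
  gs2 <- group_mean_sd(vols, pet_mask(half, diag(4)))
  expect_true(all(gs2$mean_map$values[4:6, , ] == 0))
})

test_that("z-score maps follow (group - CN)/CN-SD and exclude zero-SD voxels", {
  gm <- pet_mask(array(1L, c(5, 5, 5)), diag(4))
  cn_vols <- lapply(1:10, function(s) rand_volume(c(5, 5, 5), seed = 600 + s))
  cn <- group_mean_sd(cn_vols, gm, "CN")

  self <- zscore_map(cn, cn)
  expect_true(all(self$z_map$values[self$valid_mask$values == 1L] == 0))

  # direct arithmetic: mean 1.5 vs CN mean 1.2, CN sd 0.15 -> z = 2
  mk_stats <- function(mean_val, sd_val) {
    gs <- group_mean_sd(cn_vols, gm, "X")
    gs$mean_map$values[] <- mean_val
    gs$sd_map$values[] <- sd_val
    gs
  }
  z <- zscore_map(mk_stats(1.5, 0.1), mk_stats(1.2, 0.15))
  expect_equal(unique(as.vector(z$z_map$values[z$valid_mask$values == 1L])), 2)

  grp_vols <- lapply(1:10, function(s) rand_volume(c(5, 5, 5), seed = 700 + s))
  grp <- group_mean_sd(grp_vols, gm, "AD")
  zm <- zscore_map(grp, cn)
  # per-voxel formula loop oracle
  for (i in sample(seq_len(125), 20)) {
    if (cn$sd_map$values[i] > 0)
      expect_equal(zm$z_map$values[i],
                   (grp$mean_map$values[i] - cn$mean_map$values[i]) /
                     cn$sd_map$values[i])
  }

  # force one voxel to zero CN SD: it must drop out of the validity mask
  cn0 <- cn; cn0$sd_map$values[2, 2, 2] <- 0
  zm0 <- zscore_map(grp, cn0)
  expect_identical(zm0$valid_mask$values[2, 2, 2], 0L)
})

test_that("AD mask applies both thresholds and component de-noising", {
  gm <- pet_mask(array(1L, c(12, 12, 12)), diag(4))
  base <- lapply(1:4, function(s) rand_volume(c(12, 12, 12), seed = 800 + s))
  ad <- group_mean_sd(base, gm, "AD")
  cn <- group_mean_sd(lapply(5:8, function(s) rand_volume(c(12, 12, 12), seed = 800 + s)),
                      gm, "CN")

  # flat background below threshold, one big blob + one 2-voxel speck above
  ad$mean_map$values[] <- 1.0
  ad$sd_map$values[] <- 0.05
  blob <- array(FALSE, c(12, 12, 12)); blob[2:7, 2:7, 2:7] <- TRUE  # 216 voxels
  speck <- array(FALSE, c(12, 12, 12)); speck[11, 11, 11:12] <- TRUE
  ad$mean_map$values[blob] <- 1.4
  ad$mean_map$values[speck] <- 1.4
  cn$mean_map$values[] <- 1.0
  cn$sd_map$values[] <- 0.1
  z <- zscore_map(ad, cn)

  m <- build_ad_mask(ad, z, ad_mask_spec(min_component_voxels = 10))
  expect_identical(m$values == 1L, blob)

  # threshold boundary: mean 1.11 included, 1.09 excluded (>= 1.1 on SUVr)
  ad2 <- ad
  ad2$mean_map$values[blob] <- 1.11
  ad2$mean_map$values[speck] <- 1.09
  z2 <- zscore_map(ad2, cn)
  m2 <- build_ad_mask(ad2, z2, ad_mask_spec(min_component_voxels = 1))
  expect_identical(sum(m2$values), sum(blob))
  expect_true(all(m2$values[speck] == 0L))

  # monotone in the SUVr threshold: raising it never adds voxels
  counts <- sapply(c(1.0, 1.1, 1.2, 1.39), function(th)
    voxel_count(build_ad_mask(ad, z, ad_mask_spec(suvr_threshold = th,
                                                  min_component_voxels = 1))))
  expect_true(all(diff(counts) <= 0))

  # everything sub-threshold -> explicit empty-mask error
  ad3 <- ad; ad3$mean_map$values[] <- 1.0
  expect_error(build_ad_mask(ad3, zscore_map(ad3, cn), ad_mask_spec()), "empty")
})
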