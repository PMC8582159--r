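test_that("voxel matrix holds each subject's masked SUVr in grid order", {
  dims <- c(6, 6, 6)
  mask_vals <- array(0L, dims)
  mask_vals[c(3, 10, 40, 100, 200)] <- 1L
  mask <- pet_mask(mask_vals, diag(4))

  vols <- list(const_volume(1, dims), const_volume(2, dims), const_volume(3, dims))
  man <- write_cohort(vols, c("CN", "CN", "AD"))
  mat <- assemble_voxel_matrix(man, mask)
  expect_equal(dim(mat$values), c(3L, 5L))
  expect_equal(unname(mat$values), matrix(rep(1:3, 5), 3))
  expect_identical(mat$voxel_index, which(mask_vals == 1L))

  rv <- rand_volume(dims, seed = 21)
  man1 <- write_cohort(list(rv), "AD")
  m1 <- assemble_voxel_matrix(man1, mask)
  expect_equal(as.vector(m1$values), rv$values[which(mask_vals == 1L)],
               tolerance = 1e-6)

  # spot-check random (subject, voxel) entries against direct volume lookup
  vols2 <- lapply(1:4, function(s) rand_volume(dims, seed = 900 + s))
  man2 <- write_cohort(vols2, c("CN", "EMCI", "LMCI", "AD"))
  mat2 <- assemble_voxel_matrix(man2, mask)
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- sample(4, 1); v <- sample(5, 1)
      expect_equal(unname(mat2$values[s, v]),
                   vols2[[s]]$values[mat2$voxel_index[v]], tolerance = 1e-6)
    }
  })
  wrong <- write_cohort(list(rand_volume(c(5, 5, 5))), "CN")
  expect_error(assemble_voxel_matrix(wrong, mask), "grid mismatch")
})

test_that("k-means recovers planted structure and the k = 1 inertia closed form", {
  # 3 subjects, 80 voxels: the first 40 voxel profiles centred at 0, the
  # rest at 10 -- a 10-sigma centroid separation
  withr::with_seed(32, {
    vals <- cbind(matrix(rnorm(3 * 40, 0, 1), nrow = 3),
                  matrix(rnorm(3 * 40, 10, 1), nrow = 3))
  })
  mat <- toy_voxel_matrix(vals)
  m2 <- kmeans_cluster(mat, 2, seed = 1, n_restarts = 10)
  planted <- rep(1:2, each = 40)
  expect_equal(e1071::classAgreement(table(m2$labels, planted))$crand, 1.0)

  m1 <- kmeans_cluster(mat, 1, seed = 1)
  X1 <- t(vals)
  grand <- colMeans(X1)
  expect_equal(m1$inertia, sum(sweep(X1, 2, grand)^2))
  expect_true(all(m1$labels == 1L))

  expect_error(kmeans_cluster(mat, 100), "exceeds")
})

test_that("best-of-restarts inertia matches the exhaustive optimum on tiny instances", {
  for (s in 1:6) {
    withr::with_seed(1000 + s, {
      n <- sample(8:12, 1)       # voxels
      d <- sample(1:3, 1)        # subjects (feature dimensions)
      vals <- matrix(rnorm(d * n), nrow = d)
    })
    mat <- toy_voxel_matrix(vals)
    fit <- kmeans_cluster(mat, 2, seed = s, n_restarts = 40)
    expect_equal(fit$inertia, exhaustive_wcss(t(vals), 2), tolerance = 1e-9)
  }
  # and against stats::kmeans as an independent implementation, on an
  # instance small enough that both searches reach the global optimum
  withr::with_seed(55, vals <- matrix(rnorm(2 * 12), nrow = 2))
  mat <- toy_voxel_matrix(vals)
  mine <- kmeans_cluster(mat, 3, seed = 2, n_restarts = 150)
  ref <- withr::with_seed(2, stats::kmeans(t(vals), 3, nstart = 150, iter.max = 100))
  expect_equal(mine$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(mine$inertia, exhaustive_wcss(t(vals), 3), tolerance = 1e-9)
})

test_that("k-means is deterministic and inertia is non-increasing in k", {
  withr::with_seed(41, vals <- matrix(rnorm(5 * 50), nrow = 5))
  mat <- toy_voxel_matrix(vals)
  a <- kmeans_cluster(mat, 4, seed = 9, n_restarts = 5)
  b <- kmeans_cluster(mat, 4, seed = 9, n_restarts = 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$inertia, b$inertia)

  inertias <- sapply(1:8, function(k)
    kmeans_cluster(mat, k, seed = 9, n_restarts = 20)$inertia)
  expect_true(all(diff(inertias) <= 1e-9))

  # every label occurs
  expect_setequal(unique(a$labels), 1:4)
})

test_that("canonical relabelling orders clusters by descending mean SUVr", {
  # two clusters with means 1.2 (labelled 1) and 1.4 (labelled 2) must swap
  vals <- cbind(matrix(1.2, 2, 3), matrix(1.4, 2, 3)) +
    withr::with_seed(5, matrix(rnorm(12, 0, 0.001), 2))
  mat <- toy_voxel_matrix(vals)
  m <- kmeans_cluster(mat, 2, seed = 1)
  m_lab <- relabel_clusters(m, mat)
  expect_true(mean(vals[, m_lab$labels == 1]) > mean(vals[, m_lab$labels == 2]))
  expect_identical(relabel_clusters(m_lab, mat)$labels, m_lab$labels)  # idempotent

  # random 5-cluster model: ordering agrees with an independent sort of means
  withr::with_seed(61, vals5 <- matrix(rnorm(3 * 40, rep(seq(2, 1, length.out = 40), each = 3), 0.01), nrow = 3))
  mat5 <- toy_voxel_matrix(vals5)
  m5 <- relabel_clusters(kmeans_cluster(mat5, 5, seed = 3, n_restarts = 20), mat5)
  means <- sapply(1:5, function(c) mean(vals5[, m5$labels == c]))
  expect_identical(order(-means), 1:5)
  expect_equal(m5$cluster_mean_suvr, means, tolerance = 1e-12)
})

test_that("division masks partition the source mask and count 90 for k = 2..13", {
  withr::with_seed(71, vals <- matrix(rnorm(3 * 60, rep(c(0, 4, 8, 12), each = 45)), nrow = 3))
  mat <- toy_voxel_matrix(vals)
  models <- fit_cluster_models(mat, 2:13, seed = 4, n_restarts = 5)
  td <- withr::local_tempdir()
  paths <- export_division_masks(models, td)
  expect_length(paths, 90L)                       # sum(2:13)
  expect_length(list.files(td, pattern = "^k\\d+_cluster\\d+\\.nii\\.gz$"), 90L)

  src <- mat$source_mask
  for (m in models[c("k2", "k4", "k13")]) {
    masks <- lapply(seq_len(m$k), function(c)
      read_volume(file.path(td, sprintf("k%02d_cluster%02d.nii.gz", m$k, c)),
                  as_mask = TRUE))
    # reloaded member counts match the model
    for (c in seq_len(m$k))
      expect_identical(voxel_count(masks[[c]]), sum(m$labels == c))
    # pairwise disjoint, union equals the source mask
    expect_identical(sum(sapply(masks, voxel_count)), voxel_count(src))
    expect_identical(do.call(mask_union, masks)$values, src$values)
  }
})

test_that("silhouette values match the hand-computed pairwise formula", {
  # two tight, well-separated clusters of identical points -> all s = 1
  vals <- matrix(c(rep(0, 4), rep(100, 4)), nrow = 1)
  mat <- toy_voxel_matrix(vals)
  m <- kmeans_cluster(mat, 2, seed = 1, representation = "voxel_mean")
  rep1 <- silhouette_scores(m, mat, seed = 1)
  expect_true(all(rep1$per_voxel$silhouette == 1))
  expect_equal(rep1$overall, 1)

  # six scalar points, explicit pairwise-distance oracle
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  mat6 <- toy_voxel_matrix(matrix(x, nrow = 1))
  m6 <- kmeans_cluster(mat6, 2, seed = 1, representation = "voxel_mean")
  rep6 <- silhouette_scores(m6, mat6, seed = 1)
  expected <- sapply(seq_along(x), function(i) {
    own <- which(m6$labels == m6$labels[i]); own <- setdiff(own, i)
    other <- which(m6$labels != m6$labels[i])
    a <- mean(abs(x[own] - x[i]))
    b <- mean(abs(x[other] - x[i]))
    (b - a) / max(a, b)
  })
  expect_equal(rep6$per_voxel$silhouette, expected, tolerance = 1e-12)

  # member of a singleton cluster scores 0 by convention
  x2 <- c(0, 0.1, 0.2, 50)
  mat2 <- toy_voxel_matrix(matrix(x2, nrow = 1))
  m2 <- kmeans_cluster(mat2, 2, seed = 1, representation = "voxel_mean")
  rep2 <- silhouette_scores(m2, mat2, seed = 1)
  singleton <- which(m2$labels == which(tabulate(m2$labels) == 1L))
  expect_equal(rep2$per_voxel$silhouette[singleton], 0)
  expect_error(silhouette_scores(kmeans_cluster(mat2, 1, seed = 1), mat2), "k >= 2")
})
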