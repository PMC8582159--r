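# In-code fixtures shared across test files.

# Small random volume/mask builders on a common default affine.
rand_volume <- function(dims = c(8, 8, 8), seed = 1, affine = diag(4)) {
  withr::with_seed(seed, pet_volume(array(runif(prod(dims)), dims), affine))
}

rand_mask <- function(dims = c(10, 10, 10), p = 0.4, seed = 1, affine = diag(4)) {
  withr::with_seed(seed, pet_mask(array(rbinom(prod(dims), 1, p), dims), affine))
}

const_volume <- function(value, dims = c(4, 4, 4), affine = diag(4)) {
  pet_volume(array(value, dims), affine)
}

# Write volumes to a temp dir and return a manifest data frame pointing at
# them (the way a user-supplied cohort would arrive).
write_cohort <- function(volumes, groups, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ids <- sprintf("sub-%03d", seq_along(volumes))
  for (i in seq_along(volumes))
    write_volume(volumes[[i]], file.path(dir, paste0(ids[i], ".nii.gz")))
  m <- data.frame(subject_id = ids, group = groups,
                  scan_path = paste0(ids, ".nii.gz"),
                  scan_date = "2012-06-01", stringsAsFactors = FALSE)
  attr(m, "dir") <- dir
  m
}

# Independent flood-fill component labelling (6/18/26-connectivity) used as
# the oracle for remove_small_components / label_components.
bfs_components <- function(values, connectivity = 6L) {
  dm <- dim(values)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ,
               drop = FALSE]
  lab <- array(0L, dm)
  cur <- 0L
  for (start in which(values == 1)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1L) || any(nb > dm)) next
        nb_lin <- nb[1L] + (nb[2L] - 1L) * dm[1L] + (nb[3L] - 1L) * dm[1L] * dm[2L]
        if (values[nb_lin] == 1 && lab[nb_lin] == 0L) {
          lab[nb_lin] <- cur
          queue <- c(queue, nb_lin)
        }
      }
    }
  }
  lab
}

# Build a voxel_matrix directly from a subjects x voxels matrix (voxels on
# a synthetic line mask), for clustering unit tests.
toy_voxel_matrix <- function(values) {
  nv <- ncol(values)
  mask_vals <- array(0L, c(nv, 1, 1))
  mask_vals[seq_len(nv), 1, 1] <- 1L
  structure(list(values = values, voxel_index = seq_len(nv),
                 subject_index = rownames(values) %||% paste0("s", seq_len(nrow(values))),
                 source_mask = pet_mask(mask_vals, diag(4))),
            class = "voxel_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive k-means oracle: minimum within-cluster sum of squares over all
# assignments of n points to k non-empty clusters.
exhaustive_wcss <- function(X, k) {
  n <- nrow(X)
  stopifnot(k^n <= 4e6)
  best <- Inf
  lab <- rep(1L, n)
  repeat {
    if (length(unique(lab)) == k) {
      w <- 0
      for (c in seq_len(k)) {
        pts <- X[lab == c, , drop = FALSE]
        ctr <- colMeans(pts)
        w <- w + sum(sweep(pts, 2L, ctr)^2)
      }
      if (w < best) best <- w
    }
    # odometer increment over base-k labels
    i <- 1L
    while (i <= n) {
      lab[i] <- lab[i] + 1L
      if (lab[i] <= k) break
      lab[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# Brute-force AUC oracle: concordant + half-tied pair counting.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
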