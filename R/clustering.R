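#' Assemble the subjects-by-voxels SUVr matrix
#'
#' Loads every scan in the manifest and extracts the SUVr values at the
#' voxels of the spatial constraint mask (the AD-variance mask in the
#' standard pipeline), giving the subjects x masked-voxels matrix whose
#' columns are the items clustered downstream. Voxel (column) order is the
#' deterministic lexicographic grid order.
#'
#' @param manifest cohort manifest (see [read_manifest()]).
#' @param mask non-empty [pet_mask()] defining the voxels (columns).
#' @param reference_mask optional reference-region mask; when given, each
#'   scan is SUVr-normalised with [compute_suvr()] before sampling.
#' @return A `voxel_matrix` list: `values` (subjects x voxels), `voxel_index`
#'   (linear grid indices of the columns), `subject_index`, `source_mask`.
#' @export
assemble_voxel_matrix <- function(manifest, mask, reference_mask = NULL) {
  stopifnot(inherits(mask, "pet_mask"))
  if (voxel_count(mask) == 0L) stop("empty constraint mask")
  idx <- which(mask$values == 1L)
  paths <- manifest_scan_paths(manifest)
  vals <- matrix(NA_real_, nrow = nrow(manifest), ncol = length(idx))
  for (s in seq_len(nrow(manifest))) {
    v <- read_volume(paths[s], expected_grid = dim(mask$values))
    if (!is.null(reference_mask)) v <- compute_suvr(v, reference_mask)
    vals[s, ] <- v$values[idx]
  }
  rownames(vals) <- manifest$subject_id
  structure(list(values = vals, voxel_index = idx,
                 subject_index = manifest$subject_id, source_mask = mask),
            class = "voxel_matrix")
}

# Voxel feature representation used for clustering and silhouettes:
# points are voxels; subject_profile uses the full across-subject SUVr
# column, voxel_mean the scalar across-subject mean.
voxel_features <- function(matrix, representation) {
  representation <- match.arg(representation, c("subject_profile", "voxel_mean"))
  if (representation == "subject_profile") t(matrix$values)
  else matrix(colMeans(matrix$values), ncol = 1L)
}

# One Lloyd run from given initial centroid rows; deterministic.
# Empty clusters are re-seeded at the point currently farthest from its
# assigned centroid (ties broken by lowest point index).
lloyd_once <- function(X, centroids, max_iterations) {
  n <- nrow(X)
  k <- nrow(centroids)
  xsq <- rowSums(X^2)
  assign_prev <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(xsq, rowSums(centroids^2), `+`) - 2 * X %*% t(centroids)
    lab <- max.col(-d2, ties.method = "first")
    # resolve empty clusters before accepting the assignment
    guard <- 0L
    repeat {
      empty <- setdiff(seq_len(k), unique(lab))
      if (!length(empty)) break
      guard <- guard + 1L
      if (guard > k + 1L) {
        warning("degenerate data: fewer distinct points than clusters; ",
                "assigning deterministically by lowest index")
        for (e in empty) lab[e] <- e
        break
      }
      cur <- d2[cbind(seq_len(n), lab)]
      far <- which.max(cur)           # ties: which.max takes the lowest index
      lab[far] <- empty[1L]
      centroids[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- xsq + sum(X[far, ]^2) - 2 * X %*% X[far, ]
    }
    if (identical(lab, assign_prev) || iter >= max_iterations) {
      centroids <- rowsum(X, lab) / as.vector(table(factor(lab, seq_len(k))))
      inertia <- sum((X - centroids[lab, , drop = FALSE])^2)
      return(list(labels = lab, centroids = centroids,
                  inertia = inertia, iterations = iter))
    }
    assign_prev <- lab
    centroids <- rowsum(X, lab) / as.vector(table(factor(lab, seq_len(k))))
  }
}

#' Seeded k-means clustering of masked voxels
#'
#' Lloyd's algorithm with squared-Euclidean distance, run to the assignment
#' fixpoint or `max_iterations`, repeated over `n_restarts` seeded random
#' initialisations with the lowest-inertia solution kept. Clustered items
#' are voxels: under `subject_profile` each voxel is its across-subject SUVr
#' vector (so clusters capture covariation over the cohort); under
#' `voxel_mean` each voxel is its scalar across-subject mean.
#'
#' @param matrix a `voxel_matrix` from [assemble_voxel_matrix()].
#' @param k number of clusters (1 to the number of voxels).
#' @param seed integer seed; fixes the restart initialisations.
#' @param n_restarts random restarts (best of).
#' @param max_iterations Lloyd iteration cap per restart.
#' @param representation `"subject_profile"` (default) or `"voxel_mean"`.
#' @return A `cluster_model` list: `k`, `labels` (per matrix column, 1..k),
#'   `centroids`, `inertia`, `iterations`, seeds and settings, plus the
#'   matrix's `voxel_index` and `source_mask` for mapping back to the grid.
#' @export
kmeans_cluster <- function(matrix, k, seed = 1L, n_restarts = 25L,
                           max_iterations = 1000L,
                           representation = "subject_profile") {
  stopifnot(inherits(matrix, "voxel_matrix"))
  X <- voxel_features(matrix, representation)
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of voxels (", n, ")")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      init <- X[sample.int(n, k), , drop = FALSE]
      fit <- lloyd_once(X, init, max_iterations)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(k = as.integer(k), labels = best$labels,
                 centroids = best$centroids, inertia = best$inertia,
                 iterations = best$iterations, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 representation = match.arg(representation,
                                            c("subject_profile", "voxel_mean")),
                 voxel_index = matrix$voxel_index,
                 source_mask = matrix$source_mask),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, %d voxels, inertia %.4f (%s, %d restarts)\n",
              x$k, length(x$labels), x$inertia, x$representation, x$n_restarts))
  invisible(x)
}

#' Canonically renumber clusters
#'
#' Permutes cluster ids into a stable, documented order: descending
#' across-subject mean SUVr of member voxels, ties broken by descending
#' cluster size, then by lowest member voxel index. Cluster 1 is therefore
#' always the highest-burden cluster. Idempotent.
#'
#' @param model a `cluster_model`.
#' @param matrix the `voxel_matrix` the model was fitted on.
#' @return The model with `labels` and `centroids` permuted; component
#'   `cluster_mean_suvr` holds the ordered means.
#' @export
relabel_clusters <- function(model, matrix) {
  stopifnot(inherits(model, "cluster_model"), inherits(matrix, "voxel_matrix"))
  k <- model$k
  means <- vapply(seq_len(k), function(c)
    mean(matrix$values[, model$labels == c, drop = FALSE]), 0)
  sizes <- vapply(seq_len(k), function(c) sum(model$labels == c), 0L)
  first_vox <- vapply(seq_len(k), function(c) min(which(model$labels == c)), 0L)
  ord <- order(-means, -sizes, first_vox)
  perm <- integer(k)
  perm[ord] <- seq_len(k)                 # old id -> new id
  model$labels <- perm[model$labels]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$cluster_mean_suvr <- means[ord]
  model
}

#' Map cluster labels back to brain space
#'
#' @param model a `cluster_model`.
#' @return A [pet_volume()] holding the label (1..k) at mask voxels, 0
#'   elsewhere.
#' @export
cluster_label_map <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  msk <- model$source_mask
  lab <- array(0, dim = dim(msk$values))
  lab[model$voxel_index] <- model$labels
  pet_volume(lab, msk$affine, msk$space)
}

#' Extract one cluster's division as a binary mask
#'
#' @param model a `cluster_model`.
#' @param cluster cluster id in 1..k.
#' @return A [pet_mask()] of that cluster's member voxels.
#' @export
cluster_division_mask <- function(model, cluster) {
  stopifnot(inherits(model, "cluster_model"), cluster >= 1L, cluster <= model$k)
  msk <- model$source_mask
  out <- array(0L, dim = dim(msk$values))
  out[model$voxel_index[model$labels == cluster]] <- 1L
  pet_mask(out, msk$affine, msk$space)
}

#' Export every cluster division as a mask file
#'
#' For each fitted model (one per k) writes one binary NIfTI mask per
#' cluster; the masks of a given k partition the constraint mask exactly.
#' The default range k = 2..13 yields 90 files.
#'
#' @param models list of `cluster_model` objects (one per k).
#' @param out_dir output directory.
#' @return Character vector of the written file paths.
#' @export
export_division_masks <- function(models, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (model in models) {
    for (c in seq_len(model$k)) {
      p <- file.path(out_dir, sprintf("k%02d_cluster%02d.nii.gz", model$k, c))
      write_volume(cluster_division_mask(model, c), p)
      paths <- c(paths, p)
    }
  }
  paths
}

#' Silhouette diagnostics of a clustering
#'
#' Standard silhouette values s(i) = (b(i) - a(i)) / max(a(i), b(i)) with
#' Euclidean distance in the model's representation space; members of
#' singleton clusters score 0. For tractability at large voxel counts a
#' seeded uniform subsample is scored.
#'
#' @param model a `cluster_model` with k >= 2.
#' @param matrix the fitted `voxel_matrix`.
#' @param sample_size score all voxels when the count is at most this,
#'   otherwise a seeded subsample of this size (default 20000).
#' @param seed subsampling seed.
#' @return A `silhouette_report` list: `per_voxel` data frame (voxel column
#'   index, cluster, silhouette), `per_cluster` mean silhouettes, `overall`
#'   mean, `n_scored`.
#' @export
silhouette_scores <- function(model, matrix, sample_size = 20000L, seed = 1L) {
  stopifnot(inherits(model, "cluster_model"), inherits(matrix, "voxel_matrix"))
  if (model$k < 2L) stop("silhouette requires k >= 2")
  X <- voxel_features(matrix, model$representation)
  n <- nrow(X)
  sel <- seq_len(n)
  if (!is.null(sample_size) && n > sample_size)
    sel <- withr::with_seed(as.integer(seed),
                            sort(sample.int(n, sample_size)))
  lab <- model$labels[sel]
  if (length(unique(lab)) < 2L)
    stop("subsample covers fewer than 2 clusters; increase sample_size")
  sil <- cluster::silhouette(lab, stats::dist(X[sel, , drop = FALSE]))
  sw <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(sel))
  per_voxel <- data.frame(voxel = sel, cluster = lab, silhouette = sw)
  per_cluster <- tapply(sw, factor(lab, seq_len(model$k)), mean)
  structure(list(per_voxel = per_voxel,
                 per_cluster = as.numeric(per_cluster),
                 overall = mean(sw), n_scored = length(sel)),
            class = "silhouette_report")
}

#' Fit cluster models over a range of k
#'
#' Runs [kmeans_cluster()] for each k in `k_range` (sharing the seed
#' schedule) and canonically renumbers each model with
#' [relabel_clusters()].
#'
#' @param matrix a `voxel_matrix`.
#' @param k_range integer vector of k values (default 2:13).
#' @inheritParams kmeans_cluster
#' @return Named list of `cluster_model` objects (`"k2"`, `"k3"`, ...).
#' @export
fit_cluster_models <- function(matrix, k_range = 2:13, seed = 1L,
                               n_restarts = 25L, max_iterations = 1000L,
                               representation = "subject_profile") {
  models <- lapply(k_range, function(k)
    relabel_clusters(kmeans_cluster(matrix, k, seed = seed,
                                    n_restarts = n_restarts,
                                    max_iterations = max_iterations,
                                    representation = representation),
                     matrix))
  names(models) <- paste0("k", k_range)
  models
}
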