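#' Construct a 3D volume
#'
#' A `pet_volume` is the package's container for a scalar field on a fixed
#' template grid: a 3D numeric array plus a 4x4 voxel-to-world affine and a
#' free-text space tag (e.g. `"MNI152-2mm"` or `"phantom-40x48x40"`). All
#' pipeline stages operate on one common grid and refuse mixed grids;
#' resampling/registration is out of scope and must happen upstream.
#'
#' @param values 3D numeric array (SUV, SUVr, or z-score values).
#' @param affine 4x4 invertible voxel-to-world matrix. Defaults to an
#'   identity-orientation affine with 1 mm voxels.
#' @param space free-text space tag recorded with the volume.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, affine = NULL, space = "unknown") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (anyNA(values) || any(is.infinite(values)))
    stop("volume contains NaN/Inf values")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(values = values, affine = affine, space = as.character(space)[1L]),
            class = "pet_volume")
}

#' Construct a binary mask
#'
#' A `pet_mask` is a [pet_volume()] whose voxels are restricted to \{0, 1\};
#' it carries a cached count of 1-voxels. Used for grey matter, white matter,
#' reference-region, composite-ROI, AD-variance and cluster-division masks.
#'
#' @param values 3D array whose entries are all 0 or 1 (logical accepted).
#' @inheritParams pet_volume
#' @return An object of class `c("pet_mask", "pet_volume")`.
#' @export
pet_mask <- function(values, affine = NULL, space = "unknown") {
  if (is.logical(values)) {
    storage.mode(values) <- "integer"
  }
  if (!all(values == 0L | values == 1L))
    stop("mask values must all be 0 or 1")
  v <- pet_volume(values, affine, space)
  v$values <- array(as.integer(values), dim = dim(values))
  v$voxel_count <- sum(v$values)
  class(v) <- c("pet_mask", "pet_volume")
  v
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

#' Number of 1-voxels in a mask
#' @param mask a [pet_mask()].
#' @return Integer count of voxels set to 1.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "pet_mask"))
  mask$voxel_count
}

#' @export
print.pet_volume <- function(x, ...) {
  kind <- if (inherits(x, "pet_mask")) "pet_mask" else "pet_volume"
  cat(sprintf("<%s> grid %s, space '%s'", kind,
              paste(dim(x$values), collapse = "x"), x$space))
  if (inherits(x, "pet_mask")) cat(sprintf(", %d voxels set", x$voxel_count))
  cat("\n")
  invisible(x)
}

# Both volumes live on one grid? Grids are compared by shape and affine.
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$affine - b$affine)) <= tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s (mixed-space inputs are not supported)",
                 what, paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  invisible(TRUE)
}

#' Load a volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expected_grid optional integer triple; loading fails if the file's
#'   grid differs (guards against accidentally mixing spaces).
#' @param space optional space tag; when `NULL` the NIfTI `descrip` header
#'   field is used if set.
#' @param as_mask load as a [pet_mask()] (values must be 0/1).
#' @return A [pet_volume()] or [pet_mask()].
#' @export
read_volume <- function(path, expected_grid = NULL, space = NULL, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (length(dim(vals)) == 4L && dim(vals)[4L] == 1L)
    vals <- array(vals, dim = dim(vals)[1:3])
  if (length(dim(vals)) < 3L)   # singleton trailing dims dropped by the reader
    vals <- array(vals, dim = c(dim(vals), rep(1L, 3L - length(dim(vals)))))
  if (length(dim(vals)) != 3L) stop("not a 3D volume: ", path)
  if (!is.null(expected_grid) && !all(dim(vals) == expected_grid))
    stop(sprintf("grid mismatch for %s: expected %s, found %s", path,
                 paste(expected_grid, collapse = "x"),
                 paste(dim(vals), collapse = "x")))
  if (anyNA(vals) || any(is.infinite(vals)))
    stop("volume contains NaN/Inf values: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (is.null(space)) {
    d <- RNifti::niftiHeader(img)$descrip
    space <- if (is.character(d) && nzchar(d)) d else "unknown"
  }
  if (as_mask) pet_mask(vals, aff, space) else pet_volume(vals, aff, space)
}

#' Write a volume to a NIfTI file
#'
#' Continuous maps are stored as 32-bit float, masks as unsigned 8-bit. The
#' space tag goes into the `descrip` header field; the affine is written as
#' the sform.
#'
#' @param vol a [pet_volume()] or [pet_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  dtype <- if (inherits(vol, "pet_mask")) "uint8" else "float"
  img <- RNifti::asNifti(vol$values, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img$descrip <- substr(vol$space, 1L, 79L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Intersect two binary masks
#'
#' Voxel-wise logical AND; used wherever one mask spatially constrains
#' another (e.g. restricting the grey-matter mask to the AD-variance mask).
#'
#' @param a,b [pet_mask()] objects on the same grid.
#' @return A [pet_mask()] with 1 exactly where both inputs are 1.
#' @export
mask_intersect <- function(a, b) {
  stopifnot(inherits(a, "pet_mask"), inherits(b, "pet_mask"))
  check_same_grid(a, b, "masks")
  pet_mask(a$values * b$values, a$affine, a$space)
}

#' Union of binary masks
#' @param ... [pet_mask()] objects on one grid.
#' @return A [pet_mask()] with 1 where any input is 1.
#' @export
mask_union <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L)
  out <- ms[[1L]]$values
  for (m in ms[-1L]) {
    check_same_grid(ms[[1L]], m, "masks")
    out <- pmax(out, m$values)
  }
  pet_mask(out, ms[[1L]]$affine, ms[[1L]]$space)
}

# Linear indices of in-mask voxel pairs adjacent under the given
# connectivity; used to build the component graph.
neighbour_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  offs <- offs[keep, ]
  # half-neighbourhood: each unordered pair once
  offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
         (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
}

#' Label connected components of a mask
#'
#' @param mask a [pet_mask()].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return Integer array of the mask's shape: 0 outside the mask, component
#'   id (1-based, ordered by first voxel) inside.
#' @export
label_components <- function(mask, connectivity = 6L) {
  stopifnot(inherits(mask, "pet_mask"))
  offs <- neighbour_offsets(connectivity)
  dm <- dim(mask$values)
  lab <- array(0L, dim = dm)
  idx <- which(mask$values == 1L)
  if (length(idx) == 0L) return(lab)
  coords <- arrayInd(idx, dm)
  pos <- array(0L, dim = dm)
  pos[idx] <- seq_along(idx)          # voxel -> vertex id
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- coords
    nb[, 1L] <- nb[, 1L] + offs$dx[r]
    nb[, 2L] <- nb[, 2L] + offs$dy[r]
    nb[, 3L] <- nb[, 3L] + offs$dz[r]
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dm[1L] +
      (nb[ok, 3L] - 1L) * dm[1L] * dm[2L]
    tgt <- pos[nb_lin]
    hit <- tgt > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[ok]][hit], tgt[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Remove small connected components from a mask
#'
#' The de-noising operator applied to thresholded z-score masks: connected
#' components smaller than `min_voxels` are dropped, leaving the spatially
#' coherent signal.
#'
#' @param mask a [pet_mask()].
#' @param min_voxels minimum component size kept (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return A [pet_mask()] that is a subset of the input.
#' @export
remove_small_components <- function(mask, min_voxels = 10L, connectivity = 6L) {
  stopifnot(inherits(mask, "pet_mask"))
  if (min_voxels < 1L) stop("'min_voxels' must be >= 1")
  if (min_voxels == 1L) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  out <- array(0L, dim = dim(mask$values))
  out[lab %in% keep & lab > 0L] <- 1L
  pet_mask(out, mask$affine, mask$space)
}
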