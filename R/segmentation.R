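#' Voxelwise wash-in (relative enhancement) map
#'
#' Initial change in signal intensity from the precontrast frame P0 to the
#' early postcontrast frame P1, as a fraction of the precontrast signal:
#' `(SI(P1) - SI(P0)) / SI(P0)`. Voxels with nonpositive precontrast signal
#' cannot be normalized and are returned as `NA` (flagged, never raised).
#'
#' @param series 4D signal array (x, y, z, t) or the list returned by
#'   [generate_lesion_volume()].
#' @param protocol a [dce_protocol()]; taken from `series` when it carries
#'   one.
#' @return 3D array of wash-in fractions (1.20 means +120%), `NA` where
#'   invalid.
#' @export
relative_enhancement_map <- function(series, protocol = NULL) {
  x <- as_dce_array(series)
  if (is.null(protocol)) protocol <- attr(x, "protocol")
  pre <- frame3d(x, 1L)
  early <- frame3d(x, protocol$early_index + 1L)
  out <- (early - pre) / pre
  out[!(pre > 0)] <- NA_real_
  out
}

# One time frame as a 3D array (robust to singleton spatial dimensions).
frame3d <- function(x, j) {
  d <- dim(x)
  array(x[, , , j, drop = FALSE], d[1:3])
}

# Accepts a bare 4D array or a generate_lesion_volume() result.
as_dce_array <- function(series) {
  if (is.list(series) && !is.null(series$series)) {
    x <- series$series
    attr(x, "protocol") <- series$protocol
    return(x)
  }
  if (length(dim(series)) != 4L) stop("series must be a 4D (x,y,z,t) array")
  series
}

#' Seed-based 3D lesion segmentation
#'
#' Supervised threshold-driven region growing: starting from a seed voxel,
#' returns the 26-connected component of voxels whose wash-in meets the
#' enhancement threshold (default 33% relative signal increase, inclusive).
#'
#' @param series 4D signal array or [generate_lesion_volume()] result.
#' @param seed 1-based voxel triple (x, y, z).
#' @param protocol a [dce_protocol()]; inferred when possible.
#' @param threshold wash-in threshold (default 0.33, included).
#' @param connectivity 26 (default) or 6.
#' @return object of class `lesion_mask`: list with `voxels` (n x 3 matrix
#'   of 1-based indices), `n_voxels`, `seed`, `dim`, `threshold`.
#' @export
segment_lesion <- function(series, seed, protocol = NULL, threshold = 0.33,
                           connectivity = 26L) {
  x <- as_dce_array(series)
  if (is.null(protocol)) protocol <- attr(x, "protocol")
  d <- dim(x)[1:3]
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel outside the grid")
  washin <- relative_enhancement_map(x, protocol)
  super <- !is.na(washin) & washin >= threshold
  if (!super[seed[1], seed[2], seed[3]])
    stop("non-enhancing seed: wash-in below threshold at the seed voxel")

  offs <- neighbor_offsets(connectivity)
  visited <- array(FALSE, d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      sweep(frontier, 2, offs[k, ], "+")))
    keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    keep <- super[lin] & !visited[lin] & !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    visited[cand] <- TRUE
    frontier <- cand
  }
  vox <- which(visited, arr.ind = TRUE)
  colnames(vox) <- c("x", "y", "z")
  structure(list(voxels = vox, n_voxels = nrow(vox), seed = seed,
                 dim = d, threshold = threshold,
                 connectivity = connectivity),
            class = "lesion_mask")
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  g
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion mask: %d voxels, seed (%s), wash-in >= %g\n",
              x$n_voxels, paste(x$seed, collapse = ", "), x$threshold))
  invisible(x)
}

# Logical 3D array view of a mask.
mask_array <- function(mask) {
  a <- array(FALSE, mask$dim)
  a[mask$voxels] <- TRUE
  a
}

#' Wrap an externally supplied mask
#'
#' Accepts a logical 3D array (e.g. read from a NIfTI label volume) in
#' place of threshold segmentation, for lesions delineated manually.
#'
#' @param mask logical 3D array.
#' @param seed optional seed voxel; defaults to the mask's first voxel.
#' @return a `lesion_mask`.
#' @export
as_lesion_mask <- function(mask, seed = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  vox <- which(mask != 0, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty mask")
  colnames(vox) <- c("x", "y", "z")
  if (is.null(seed)) seed <- as.integer(vox[1, ])
  structure(list(voxels = vox, n_voxels = nrow(vox), seed = seed,
                 dim = dim(mask), threshold = NA_real_,
                 connectivity = NA_integer_),
            class = "lesion_mask")
}
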