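#' Body mask from a CT volume
#'
#' Thresholds the CT volume at `hu_threshold` and keeps the largest
#' 6-connected component, standing in for the imaged body part.
#'
#' @param ct `voxvol` with units `"HU"`.
#' @param hu_threshold voxels with HU strictly above this belong to the
#'   candidate body (default -900, between air and inflated lung, so lungs
#'   belong to the body).
#' @return A `voxvol` with units `"mask"` (0/1).
#' @export
make_body_mask <- function(ct, hu_threshold = -900) {
  m <- unclass(ct) > hu_threshold
  if (!any(m)) stop("empty body mask: no voxel above threshold")
  lab <- .label_components6(as.logical(m), dim(ct))
  tab <- tabulate(lab)
  keep <- which.max(tab)
  out <- array(as.numeric(lab == keep), dim(ct))
  new_like(ct, out, units = "mask")
}

#' Enumerate overlapping patch positions
#'
#' Generates the regular grid of patch corner positions used for
#' patch-based training: corners at multiples of the offsets (7 voxels
#' transverse, 5 axial by default) keeping the whole patch inside the
#' volume, in lexicographic corner order.  Patches containing less than
#' `min_fraction` of body-mask voxels are excluded (the default 1/8
#' mirrors the exclusion of patches with less than one eighth of the
#' imaged body part).
#'
#' @param volume_dims integer triple.
#' @param patch_dims integer triple, default `c(48, 48, 24)`.
#' @param offsets integer triple of strides, default `c(7, 7, 5)`.
#' @param mask optional body mask (`voxvol` or array); `NULL` counts every
#'   voxel as body.
#' @param min_fraction minimum body fraction a patch must contain.
#' @return data.frame with 0-based corner columns `x0`, `y0`, `z0` and
#'   `body_fraction`; attribute `n_candidates` holds the pre-exclusion
#'   count.
#' @export
enumerate_patches <- function(volume_dims, patch_dims = c(48, 48, 24),
                              offsets = c(7, 7, 5), mask = NULL,
                              min_fraction = 1 / 8) {
  volume_dims <- as.integer(volume_dims)
  patch_dims <- as.integer(patch_dims)
  offsets <- as.integer(offsets)
  if (any(patch_dims > volume_dims))
    stop("patch larger than volume")
  starts <- lapply(1:3, function(a)
    seq.int(0L, volume_dims[a] - patch_dims[a], by = offsets[a]))
  grid <- expand.grid(x0 = starts[[1]], y0 = starts[[2]], z0 = starts[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic by corner (x fastest, then y, then z) = expand.grid order
  n_cand <- nrow(grid)
  if (is.null(mask)) {
    frac <- rep(1, n_cand)
  } else {
    m <- array(as.numeric(unclass(mask) != 0), volume_dims)
    # summed-volume table for O(1) per-patch body counts
    cs <- apply(apply(apply(m, c(2, 3), cumsum), c(1, 3), cumsum),
                c(1, 2), cumsum)
    cs <- aperm(cs, c(2, 3, 1))
    pad <- array(0, volume_dims + 1L)
    pad[-1, -1, -1] <- cs
    x0 <- grid$x0; y0 <- grid$y0; z0 <- grid$z0
    x1 <- x0 + patch_dims[1]; y1 <- y0 + patch_dims[2]
    z1 <- z0 + patch_dims[3]
    box <- function(i, j, k) pad[cbind(i + 1L, j + 1L, k + 1L)]
    cnt <- box(x1, y1, z1) - box(x0, y1, z1) - box(x1, y0, z1) -
      box(x1, y1, z0) + box(x0, y0, z1) + box(x0, y1, z0) +
      box(x1, y0, z0) - box(x0, y0, z0)
    frac <- cnt / prod(patch_dims)
  }
  grid$body_fraction <- frac
  out <- grid[frac >= min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- n_cand
  attr(out, "patch_dims") <- patch_dims
  out
}

#' Cap a patch index to a fixed count
#'
#' Uniform seed-controlled subsampling used when a fixed per-image patch
#' budget (e.g. 5,000) is smaller than the number of surviving positions;
#' fewer positions than the cap are returned unchanged.
#'
#' @param index data.frame from [enumerate_patches()].
#' @param n_max maximum number of patches.
#' @param seed integer seed.
#' @return Subset of `index` (original corner order preserved).
#' @export
cap_patches <- function(index, n_max, seed = 1L) {
  if (nrow(index) <= n_max) return(index)
  keep <- sort(sample_int_seeded(nrow(index), n_max, seed))
  out <- index[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "patch_dims") <- attr(index, "patch_dims")
  out
}

# seed-local sampling that does not disturb the caller's RNG stream
sample_int_seeded <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(n, k)
}

#' Extract aligned patches from co-registered volumes
#'
#' Crops the same patch positions out of each supplied volume (e.g. PET,
#' CT and dose-rate), returning aligned 4D stacks in index order.  No
#' normalization is applied at this stage.
#'
#' @param volumes named list of `voxvol`s on one grid.
#' @param index data.frame from [enumerate_patches()] (needs its
#'   `patch_dims` attribute or an explicit `patch_dims`).
#' @param patch_dims integer triple; defaults to the index attribute.
#' @return A `patch_set`: list with `index`, `patch_dims` and one 4D array
#'   `[x, y, z, patch]` per input volume.
#' @export
extract_patches <- function(volumes, index, patch_dims = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1)
  do.call(check_same_grid, unname(volumes))
  if (is.null(patch_dims)) patch_dims <- attr(index, "patch_dims")
  if (is.null(patch_dims)) stop("patch_dims not given")
  pd <- as.integer(patch_dims)
  np <- nrow(index)
  vd <- dim(volumes[[1]])
  if (np > 0 && (any(index$x0 + pd[1] > vd[1]) ||
                 any(index$y0 + pd[2] > vd[2]) ||
                 any(index$z0 + pd[3] > vd[3])))
    stop("patch index out of bounds for these volumes")
  stacks <- lapply(volumes, function(v) {
    a <- array(0, c(pd, np))
    vv <- unclass(v)
    for (p in seq_len(np)) {
      a[, , , p] <- vv[index$x0[p] + seq_len(pd[1]),
                       index$y0[p] + seq_len(pd[2]),
                       index$z0[p] + seq_len(pd[3])]
    }
    a
  })
  structure(c(list(index = index, patch_dims = pd), stacks),
            class = "patch_set")
}

#' Reassemble patch predictions into a volume
#'
#' Writes predicted patches back at their corner positions, averaging
#' overlapping predictions with uniform weights per covering patch.
#' Returns the assembled volume together with the coverage-count map;
#' voxels covered by no patch are zero and reported.
#'
#' @param index data.frame of patch corners (0-based).
#' @param predicted 4D array `[x, y, z, patch]` aligned with `index`.
#' @param volume_dims integer triple of the output volume.
#' @param voxel_size mm triple for the output `voxvol`.
#' @param units units tag of the output (default `"Gy/s"`).
#' @param mask optional body mask; uncovered body voxels trigger a warning.
#' @return A `voxvol` with attribute `coverage` (integer array of covering
#'   patch counts).
#' @export
assemble_prediction <- function(index, predicted, volume_dims, voxel_size,
                                units = "Gy/s", mask = NULL) {
  pd <- dim(predicted)[1:3]
  np <- dim(predicted)[4]
  stopifnot(np == nrow(index))
  acc <- array(0, volume_dims)
  cov <- array(0L, volume_dims)
  for (p in seq_len(np)) {
    ix <- index$x0[p] + seq_len(pd[1])
    iy <- index$y0[p] + seq_len(pd[2])
    iz <- index$z0[p] + seq_len(pd[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + predicted[, , , p]
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1L
  }
  out <- ifelse(cov > 0L, acc / pmax(cov, 1L), 0)
  dim(out) <- volume_dims
  if (!is.null(mask)) {
    miss <- sum(unclass(mask) != 0 & cov == 0L)
    if (miss > 0)
      warning(sprintf("%d body voxels not covered by any patch", miss))
  }
  v <- voxvol(out, voxel_size, units)
  attr(v, "coverage") <- cov
  v
}

#' Training-set bookkeeping
#'
#' Computes the total number of training patches for a study design:
#' subjects x time points x patches per static image (the per-image count
#' after exclusion, capped at `patches_per_image`).
#'
#' @param n_subjects number of subjects.
#' @param n_time_points frames per subject.
#' @param patches_per_image patch budget per static image (default 5000).
#' @return Total patch count.
#' @export
training_set_size <- function(n_subjects, n_time_points,
                              patches_per_image = 5000) {
  n_subjects * n_time_points * patches_per_image
}
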