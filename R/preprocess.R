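# Gaussian FWHM -> standard deviation conversion factor
FWHM_TO_SIGMA <- 1 / sqrt(8 * log(2))

# Apply a linear operator `op` (a matrix acting on one axis) along `axis`
# of a 3-D array. Used for both separable Gaussian convolution and block
# averaging; the operator rows may change the axis length.
apply_along_axis <- function(arr, op, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- op %*% matrix(a, nrow = d[axis])
  d_out <- d
  d_out[axis] <- nrow(op)
  out <- array(m, dim = d_out[perm])
  aperm(out, order(perm))
}

# Band matrix realizing zero-padded discrete Gaussian convolution of a
# length-n axis with standard deviation sigma (in voxels). The truncated
# kernel is renormalized per output voxel, so constants are preserved
# everywhere; interior columns still sum to one, so mass is conserved for
# any blob supported away from the boundary.
gaussian_band_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  taps <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  taps <- taps / sum(taps)
  op <- matrix(0, n, n)
  for (k in seq(-r, r)) {
    idx <- seq_len(n)
    j <- idx + k
    keep <- j >= 1L & j <= n
    op[cbind(idx[keep], j[keep])] <- op[cbind(idx[keep], j[keep])] +
      taps[k + r + 1L]
  }
  op / rowSums(op)
}

#' Smooth a gray-matter volume with a Gaussian kernel
#'
#' Separable Gaussian filtering with the kernel size given as full width at
#' half maximum in millimetres; the per-axis standard deviation in voxels is
#' `fwhm_mm / (spacing_mm[axis] * sqrt(8 * log(2)))`. Boundaries are
#' zero-padded with the truncated kernel renormalized per voxel: constant
#' maps pass through unchanged, and mass is conserved for gray matter
#' supported away from the grid edge, as segmented maps are.
#'
#' @param vol A [gm_volume()].
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0).
#' @return The smoothed [gm_volume()] on the same grid.
#' @export
smooth_volume <- function(vol, fwhm_mm = 8) {
  stopifnot(inherits(vol, "gm_volume"))
  stop_if_not_scalar_number(fwhm_mm, "fwhm_mm")
  if (fwhm_mm <= 0) abort("`fwhm_mm` must be positive.")
  out <- vol$data
  for (axis in 1:3) {
    sigma <- fwhm_mm * FWHM_TO_SIGMA / vol$spacing_mm[axis]
    op <- gaussian_band_matrix(dim(out)[axis], sigma)
    out <- apply_along_axis(out, op, axis)
  }
  vol$data <- out
  vol
}

# Aggregation matrix mapping n_fine voxels of size `fine` mm onto coarse
# voxels of size `coarse` mm: each coarse voxel averages the fine voxels
# whose centres fall in its world footprint.
block_average_matrix <- function(n_fine, fine, coarse) {
  centres <- (seq_len(n_fine) - 0.5) * fine
  grp <- pmin(floor(centres / coarse) + 1L, ceiling(n_fine * fine / coarse))
  n_coarse <- max(grp)
  op <- matrix(0, n_coarse, n_fine)
  op[cbind(grp, seq_len(n_fine))] <- 1
  op / rowSums(op)
}

#' Resample a volume to a coarser isotropic grid
#'
#' Downsamples to an isotropic grid at `target_spacing_mm` covering the same
#' world extent, by block-averaging the fine voxels falling inside each
#' coarse voxel's footprint. Block averaging is deterministic, preserves the
#' mean up to edge effects, and creates no new extrema.
#'
#' @param vol A [gm_volume()].
#' @param target_spacing_mm Desired isotropic voxel size in mm; must be at
#'   least the largest source spacing (this is a downsampling operation).
#' @return A [gm_volume()] with spacing `rep(target_spacing_mm, 3)`.
#' @export
resample_volume <- function(vol, target_spacing_mm = 8) {
  stopifnot(inherits(vol, "gm_volume"))
  stop_if_not_scalar_number(target_spacing_mm, "target_spacing_mm")
  if (target_spacing_mm <= 0) abort("`target_spacing_mm` must be positive.")
  if (target_spacing_mm < max(vol$spacing_mm)) {
    abort("`target_spacing_mm` must be >= the source spacing (downsampling).")
  }
  out <- vol$data
  for (axis in 1:3) {
    op <- block_average_matrix(dim(out)[axis], vol$spacing_mm[axis],
                               target_spacing_mm)
    out <- apply_along_axis(out, op, axis)
  }
  vol$data <- out
  vol$spacing_mm <- rep(target_spacing_mm, 3)
  vol
}

#' Build a gray-matter analysis mask from training volumes
#'
#' The mask is true where the mean gray-matter density across the supplied
#' volumes exceeds `threshold`. The default 0.1 is permissive: it only drops
#' empty background, keeping the analysis close to using the whole smoothed
#' image; set `threshold = 0` to keep every voxel with any gray matter.
#'
#' @param volumes A list of [gm_volume()] objects on a common grid.
#' @param threshold Mean-density threshold in \[0, 1\].
#' @return An object of class `gm_mask` with fields `mask` (logical array)
#'   and `voxel_count`.
#' @export
build_mask <- function(volumes, threshold = 0.1) {
  if (length(volumes) < 1L) abort("need at least one volume to build a mask.")
  ref <- dim(volumes[[1]]$data)
  for (v in volumes) {
    if (!identical(dim(v$data), ref)) {
      abort(sprintf("grid mismatch: subject '%s' has dimensions %s, expected %s.",
                    v$subject_id, paste(dim(v$data), collapse = "x"),
                    paste(ref, collapse = "x")))
    }
  }
  acc <- Reduce(`+`, lapply(volumes, function(v) v$data))
  m <- (acc / length(volumes)) > threshold
  structure(list(mask = m, voxel_count = sum(m), dim = ref,
                 threshold = threshold),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("<gm_mask> %s grid, %d voxels in mask (threshold %g)\n",
              paste(x$dim, collapse = "x"), x$voxel_count, x$threshold))
  invisible(x)
}

#' Vectorize a volume under a mask
#'
#' Extracts the masked voxels as a feature vector in a fixed ordering: the
#' array's storage order, first axis fastest-varying (R column-major order).
#' The ordering is identical for every subject on the same grid.
#'
#' @param vol A [gm_volume()].
#' @param mask A [build_mask()] result congruent with the volume grid.
#' @return Named numeric vector of length `mask$voxel_count` with attribute
#'   `subject_id`.
#' @export
vectorize <- function(vol, mask) {
  stopifnot(inherits(vol, "gm_volume"), inherits(mask, "gm_mask"))
  if (!identical(dim(vol$data), mask$dim)) {
    abort(sprintf("grid mismatch: subject '%s' does not match the mask grid.",
                  vol$subject_id))
  }
  if (mask$voxel_count == 0L) abort("empty feature space: mask has no voxels.")
  out <- vol$data[mask$mask]
  attr(out, "subject_id") <- vol$subject_id
  out
}

#' Scatter a feature vector back into a volume
#'
#' Inverse of [vectorize()]: places feature values back at their masked
#' voxel positions (zero elsewhere).
#'
#' @param values Numeric vector of length `mask$voxel_count`.
#' @param mask A [build_mask()] result.
#' @return A 3-D array.
#' @export
scatter_features <- function(values, mask) {
  stopifnot(inherits(mask, "gm_mask"))
  if (length(values) != mask$voxel_count) {
    abort("feature length does not match mask voxel count.")
  }
  out <- array(0, dim = mask$dim)
  out[mask$mask] <- values
  out
}

#' Run the full feature-extraction pipeline on a set of volumes
#'
#' Smooths each volume (default 8 mm FWHM), resamples to a coarse isotropic
#' grid (default 8 mm), builds (or reuses) a background-excluding mask, and
#' vectorizes every subject into the rows of a feature matrix. When scoring
#' test subjects, pass the mask obtained from the training sample so that
#' train and test share an identical feature space.
#'
#' @param volumes Named list of [gm_volume()] objects.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param target_spacing_mm Final isotropic voxel size in mm.
#' @param mask_threshold Mean-density threshold for [build_mask()].
#' @param mask Optional precomputed `gm_mask` (from the training sample).
#' @return A list with `features` (subjects x voxels matrix, rownames =
#'   subject ids), `mask`, and `mask_checksum`.
#' @export
extract_features <- function(volumes, fwhm_mm = 8, target_spacing_mm = 8,
                             mask_threshold = 0.1, mask = NULL) {
  processed <- lapply(volumes, function(v) {
    resample_volume(smooth_volume(v, fwhm_mm), target_spacing_mm)
  })
  if (is.null(mask)) mask <- build_mask(processed, mask_threshold)
  rows <- lapply(processed, vectorize, mask = mask)
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(processed, function(v) v$subject_id, "")
  list(features = features, mask = mask, mask_checksum = rlang::hash(mask))
}
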