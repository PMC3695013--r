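#' Gray-matter volume objects
#'
#' A `gm_volume` wraps a 3-D array of gray-matter density (tissue
#' probability, expected range \[0, 1\]) together with its voxel spacing in
#' millimetres and a subject identifier. Volumes are assumed to be already
#' bias-corrected, spatially normalized and tissue-segmented upstream; this
#' package only smooths, resamples and vectorizes them.
#'
#' @param data 3-D numeric array of gray-matter density.
#' @param spacing_mm Numeric vector of length 3, voxel edge lengths in mm
#'   (all strictly positive).
#' @param subject_id Character scalar identifying the subject.
#' @param origin_mm World-space position (mm) of the first voxel centre.
#'
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, spacing_mm, subject_id = "unknown",
                      origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array; expected 3-D volume.")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 positive voxel sizes in mm.")
  }
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L) {
    abort(sprintf("volume '%s' contains %d non-finite voxel(s).",
                  subject_id, n_bad))
  }
  out_of_range <- sum(data < 0 | data > 1)
  vol <- structure(
    list(data = data, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm),
         subject_id = as.character(subject_id)),
    class = "gm_volume"
  )
  if (out_of_range > 0L) {
    # flagged, never clipped: downstream code decides what to do
    attr(vol, "n_out_of_range") <- out_of_range
    warn(sprintf(
      "volume '%s': %d voxel(s) outside [0, 1]; values kept as stored.",
      subject_id, out_of_range))
  }
  vol
}

#' @export
print.gm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gm_volume '%s'> %dx%dx%d voxels @ %.3gx%.3gx%.3g mm\n",
              x$subject_id, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Read a gray-matter probability volume from NIfTI
#'
#' Reads a 3-D NIfTI-1 image (`.nii` or `.nii.gz`) and returns it as a
#' [gm_volume()] with the stored grid and voxel spacing, untouched: no
#' resampling or rescaling is applied. Non-finite voxels are an error;
#' values outside \[0, 1\] are flagged with a warning but never clipped.
#'
#' @param path Path to a NIfTI file.
#' @param subject_id Identifier for the subject; defaults to the file name
#'   without extension.
#' @return A [gm_volume()].
#' @export
read_gm_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("NIfTI file not found: '%s'", path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    abort(sprintf("'%s': expected 3-D volume, got %d dimension(s).",
                  path, length(d)))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  n_bad <- sum(!is.finite(img))
  if (n_bad > 0L) {
    abort(sprintf("'%s' contains %d non-finite voxel(s).", path, n_bad))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  gm_volume(array(as.numeric(img), dim = d), spacing_mm = spacing,
            subject_id = subject_id)
}

#' Write a gray-matter volume to NIfTI
#'
#' @param vol A [gm_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gm_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
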