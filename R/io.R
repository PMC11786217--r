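# NIfTI mask I/O.
#
# Masks travel as NIfTI volumes whose affine encodes spacing and origin;
# on read they are conformed to the package's RAS-like convention (third
# array axis = inferior-superior) and to the canonical 1 mm isotropic grid.

#' Write a lesion mask as NIfTI
#'
#' The sform affine encodes the voxel spacing on its diagonal and the
#' physical coordinate of the first voxel center as its translation.
#'
#' @param mask A [mask3d].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_mask3d(mask))
  img <- RNifti::asNifti(mask$occupancy)
  RNifti::pixdim(img) <- mask$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- mask$spacing
  aff[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lesion mask from NIfTI
#'
#' Occupancy is binarized (non-zero = occupied). Axis flips encoded in the
#' affine (negative diagonal) are undone so the result follows the RAS
#' convention; non-axis-aligned affines are rejected. If the file's voxel
#' spacing differs from the canonical spacing the mask is auto-resampled
#' (nearest neighbor) with a warning, matching the preprocessing convention
#' that all contours live on a 1 mm isotropic grid.
#'
#' @param path NIfTI file.
#' @param conform_spacing Canonical spacing in mm (default 1); `NA`
#'   disables resampling.
#' @return A [mask3d].
#' @export
read_mask <- function(path, conform_spacing = 1) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop_ranobm(sprintf("cannot read NIfTI mask '%s': %s", path,
                        conditionMessage(e)),
                "ranobm_io_error")
  })
  arr <- as.array(img)
  nd <- length(dim(arr) %||% length(arr))
  if (nd < 3L) {  # singleton trailing dims dropped by the writer
    dim(arr) <- c(dim(arr) %||% length(arr), rep(1L, 3L - nd))
  }
  if (length(dim(arr)) != 3L) {
    stop_ranobm(sprintf("'%s' is not a 3D volume", path), "ranobm_io_error")
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dircos <- sweep(rot, 2L, spacing, `/`)
  if (any(abs(abs(dircos) - diag(3)) > 1e-4 & abs(dircos) > 1e-4)) {
    stop_ranobm(sprintf("'%s' has a non-axis-aligned affine", path),
                "ranobm_io_error")
  }
  origin <- xf[1:3, 4]
  # undo axis flips so the stored array runs in +RAS direction
  for (a in 1:3) {
    if (dircos[a, a] < 0) {
      idx <- rev(seq_len(dim(arr)[a]))
      arr <- switch(a, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      origin[a] <- origin[a] - (dim(arr)[a] - 1) * spacing[a]
    }
  }
  m <- mask3d(arr != 0, spacing, origin)
  if (!is.na(conform_spacing) &&
      !isTRUE(all.equal(m$spacing, rep(conform_spacing, 3)))) {
    warning(sprintf(
      "'%s' has spacing %s mm; auto-resampling to %g mm isotropic",
      basename(path), paste(format(spacing), collapse = "x"),
      conform_spacing))
    m <- resample_mask(m, conform_spacing)
  }
  m
}
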