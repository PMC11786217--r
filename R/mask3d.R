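#' Binary lesion mask on a regular voxel grid
#'
#' `mask3d` is the geometric substrate of every size measurement in the
#' package: a 3D binary occupancy array with physical voxel spacing and the
#' physical coordinate of the first voxel center. The axis convention is
#' RAS-like with the third array dimension the inferior-superior (z) axis,
#' so axial slices are fixed-z planes `occ[, , k]`.
#'
#' @param occupancy 3D array coercible to 0/1 integer.
#' @param spacing Numeric length-3 (or scalar, recycled) voxel spacing in mm;
#'   strictly positive.
#' @param origin Numeric length-3 physical coordinate (mm) of the center of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `mask3d`.
#' @export
#' @examples
#' m <- mask3d(array(1L, c(3, 3, 3)))
#' volume_mm3(m)
mask3d <- function(occupancy, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L) {
    stop_ranobm("occupancy must be a 3D array", "ranobm_invalid_mask")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_ranobm("spacing must be strictly positive", "ranobm_invalid_mask")
  }
  occ <- array(as.integer(occupancy != 0), dim = dim(occupancy))
  structure(
    list(occupancy = occ, spacing = spacing,
         origin = rep_len(as.numeric(origin), 3L)),
    class = "mask3d"
  )
}

#' @export
print.mask3d <- function(x, ...) {
  n <- sum(x$occupancy)
  cat(sprintf(
    "<mask3d> %s voxels, %d occupied, spacing %s mm, volume %.1f mm^3\n",
    paste(dim(x$occupancy), collapse = "x"), n,
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    n * prod(x$spacing)
  ))
  invisible(x)
}

#' Test for the mask3d class / emptiness
#' @param x Object.
#' @return Logical scalar.
#' @export
is_mask3d <- function(x) inherits(x, "mask3d")

#' @rdname is_mask3d
#' @export
is_empty_mask <- function(x) {
  stopifnot(is_mask3d(x))
  sum(x$occupancy) == 0L
}

# Physical coordinates (mm) of the centers of occupied voxels, n x 3.
occupied_coords <- function(mask) {
  idx <- which(mask$occupancy != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  sweep(sweep(idx - 1, 2L, mask$spacing, `*`), 2L, mask$origin, `+`)
}

# Occupancy centroid in physical mm.
mask_centroid <- function(mask) {
  xyz <- occupied_coords(mask)
  if (nrow(xyz) == 0L) {
    stop_ranobm("centroid of an empty mask is undefined", "ranobm_empty_mask")
  }
  colMeans(xyz)
}

#' Pad a mask grid with empty voxels on every side
#'
#' Rotation resampling requires headroom so occupied voxels cannot be
#' clipped at the grid boundary; `pad_mask` grows the grid symmetrically,
#' shifting the origin so physical coordinates are unchanged.
#'
#' @param mask A [mask3d].
#' @param voxels Non-negative integer, number of empty voxels added per side
#'   (scalar or length 3).
#' @return A [mask3d] on the enlarged grid.
#' @export
pad_mask <- function(mask, voxels) {
  stopifnot(is_mask3d(mask))
  v <- rep_len(as.integer(voxels), 3L)
  if (any(v < 0L)) stop_ranobm("pad must be non-negative", "ranobm_invalid_mask")
  d <- dim(mask$occupancy)
  occ <- array(0L, d + 2L * v)
  occ[v[1] + seq_len(d[1]), v[2] + seq_len(d[2]), v[3] + seq_len(d[3])] <-
    mask$occupancy
  mask3d(occ, mask$spacing, mask$origin - v * mask$spacing)
}

# Crop a mask to the bounding box of its occupied voxels plus a margin
# (in voxels). Used to keep generated cohorts memory-light.
crop_mask <- function(mask, margin = 2L) {
  idx <- which(mask$occupancy != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask)
  d <- dim(mask$occupancy)
  lo <- pmax(apply(idx, 2L, min) - margin, 1L)
  hi <- pmin(apply(idx, 2L, max) + margin, d)
  occ <- mask$occupancy[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask3d(occ, mask$spacing, mask$origin + (lo - 1L) * mask$spacing)
}
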