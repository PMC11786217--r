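# Geometric measurement of lesion masks.
#
# Everything downstream (response classification, stability, agreement)
# consumes the two size measures defined here: voxel-count volume and the
# longest axial diameter, i.e. the maximum in-plane Feret diameter over
# fixed-z slices, as measured in clinical practice.

#' Lesion volume from voxel occupancy
#'
#' Volume is the count of occupied voxels times the voxel volume. At the
#' canonical 1 mm isotropic spacing this is simply the voxel count.
#'
#' @param mask A [mask3d].
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
#' @examples
#' volume_mm3(mask3d(array(1L, c(10, 10, 10))))  # 1000
volume_mm3 <- function(mask) {
  stopifnot(is_mask3d(mask))
  sum(mask$occupancy) * prod(mask$spacing)
}

#' Longest axial diameter of a lesion mask
#'
#' For every axial (fixed-z) slice, the maximum center-to-center distance
#' between occupied voxels within the slice is computed (the in-plane
#' maximum Feret diameter); the largest value over slices is returned.
#' Diameters are deliberately restricted to axial planes: a lesion elongated
#' along the inferior-superior axis is measured by its largest axial
#' cross-section, not by its 3D extent. A slice with a single occupied voxel
#' contributes 0 mm.
#'
#' The implementation takes the convex hull of each slice's occupied voxel
#' centers before the pairwise scan; the exhaustive O(n^2) scan over all
#' occupied voxels gives identical results and serves as the test oracle.
#'
#' @param mask A [mask3d].
#' @return Diameter in mm (0 for an empty mask).
#' @export
longest_axial_diameter <- function(mask) {
  stopifnot(is_mask3d(mask))
  occ <- mask$occupancy
  if (sum(occ) == 0L) return(0)
  sp <- mask$spacing
  best <- 0
  for (k in seq_len(dim(occ)[3])) {
    idx <- which(occ[, , k] != 0L, arr.ind = TRUE)
    if (nrow(idx) < 2L) next
    pts <- cbind(idx[, 1] * sp[1], idx[, 2] * sp[2])
    if (nrow(pts) > 3L) {
      h <- tryCatch(grDevices::chull(pts), error = function(e) seq_len(nrow(pts)))
      pts <- pts[h, , drop = FALSE]
    }
    d <- max(stats::dist(pts))
    if (d > best) best <- d
  }
  best
}

#' Cube-root lesion size
#'
#' Maps a volume to a length scale comparable with diameters; used when
#' pooling volumetric and unidimensional coefficients of variation so that
#' the two kinds of measure are compared on the same (linear) scale.
#'
#' @param volume Volume in mm^3, non-negative.
#' @return `volume^(1/3)` in mm.
#' @export
cube_root_size <- function(volume) {
  if (any(volume < 0)) {
    stop_ranobm("volume must be non-negative", "ranobm_invalid_value")
  }
  volume^(1 / 3)
}

#' Arithmetic set of rotation angles including zero
#'
#' @param min_deg,max_deg Range in degrees, `min_deg <= 0 <= max_deg`.
#' @param step Positive step in degrees dividing the range.
#' @return Numeric vector of angles; always contains 0.
#' @export
#' @examples
#' length(rotation_set(-20, 20, 2))  # 21
rotation_set <- function(min_deg, max_deg, step) {
  if (step <= 0) stop_ranobm("step must be positive", "ranobm_invalid_value")
  if (min_deg > 0 || max_deg < 0) {
    stop_ranobm("range must include 0", "ranobm_invalid_value")
  }
  angles <- seq(min_deg, max_deg, by = step)
  if (!any(angles == 0)) {
    stop_ranobm("0 degrees is not representable with this min/step",
                "ranobm_invalid_value")
  }
  angles
}

#' Rotation specification for stability analyses
#'
#' @param angles Degree vector, must contain 0 (see [rotation_set]).
#' @param axes `"x"` for single-axis rotation about the patient x-axis, or
#'   `"xyz"` for the extreme mode composing rotations of the same angle
#'   about x, then y, then z (in that fixed order; composition is
#'   non-commutative and the order is part of the contract).
#' @param center Optional rotation center in mm; defaults to the occupancy
#'   centroid of the rotated mask.
#' @return A `rotation_spec` list.
#' @export
rotation_spec <- function(angles = rotation_set(-20, 20, 2),
                          axes = c("x", "xyz"), center = NULL) {
  axes <- match.arg(axes)
  if (!any(angles == 0)) {
    stop_ranobm("angle set must include 0", "ranobm_invalid_value")
  }
  structure(list(angles = angles, axes = axes, center = center),
            class = "rotation_spec")
}

rotation_matrix <- function(angle_deg, axes = "x") {
  # cospi/sinpi keep multiples of 90 degrees exact, so axis-aligned
  # rotations are exact lattice permutations.
  a <- angle_deg / 180
  cs <- cospi(a); sn <- sinpi(a)
  rx <- matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3, 3)
  if (axes == "x") return(rx)
  ry <- matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3, 3)
  rz <- matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx  # applied x first, then y, then z
}

#' Rigid rotation of a lesion mask about its centroid
#'
#' Applies a rigid rotation with nearest-neighbor occupancy resampling at
#' the native grid spacing, emulating a change in patient head orientation.
#' The rotation center is the voxel center nearest the occupancy centroid
#' (snapping to the lattice makes 90-degree axis-aligned rotations exact
#' voxel permutations). If the rotation would carry any occupied voxel
#' outside the grid, an error is raised: pad first with [pad_mask].
#'
#' @param mask A non-degenerate [mask3d].
#' @param angle Angle in degrees.
#' @param axes `"x"` or `"xyz"` (see [rotation_spec]).
#' @param center Optional rotation center (mm); snapped to the nearest
#'   voxel center.
#' @return The rotated [mask3d] on the same grid.
#' @export
rotate_mask <- function(mask, angle, axes = c("x", "xyz"), center = NULL) {
  stopifnot(is_mask3d(mask))
  axes <- match.arg(axes)
  if (angle == 0) return(mask)
  if (is_empty_mask(mask)) {
    stop_ranobm("cannot rotate an empty mask", "ranobm_empty_mask")
  }
  sp <- mask$spacing; org <- mask$origin; d <- dim(mask$occupancy)
  ctr <- center %||% mask_centroid(mask)
  ctr <- org + round((ctr - org) / sp) * sp  # snap to voxel center

  rot <- rotation_matrix(angle, axes)

  # Clipping check: forward-rotate occupied voxel centers.
  fwd <- occupied_coords(mask)
  fwd <- sweep(sweep(fwd, 2L, ctr) %*% t(rot), 2L, ctr, `+`)
  lo <- org - sp / 2
  hi <- org + (d - 1) * sp + sp / 2
  if (any(fwd[, 1] < lo[1] | fwd[, 1] > hi[1] |
          fwd[, 2] < lo[2] | fwd[, 2] > hi[2] |
          fwd[, 3] < lo[3] | fwd[, 3] > hi[3])) {
    stop_ranobm(
      sprintf("rotation by %g degrees clips occupied voxels; pad the grid",
              angle),
      "ranobm_rotation_clipped"
    )
  }

  # Inverse mapping with nearest-neighbor lookup.
  gx <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  gy <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  gz <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  pts <- cbind(rep(gx, times = d[2] * d[3]),
               rep(rep(gy, each = d[1]), times = d[3]),
               rep(gz, each = d[1] * d[2]))
  q <- sweep(sweep(pts, 2L, ctr) %*% rot, 2L, ctr, `+`)  # R^T via %*% rot
  ii <- round((q[, 1] - org[1]) / sp[1]) + 1
  jj <- round((q[, 2] - org[2]) / sp[2]) + 1
  kk <- round((q[, 3] - org[3]) / sp[3]) + 1
  ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
  occ <- integer(nrow(pts))
  lin <- (kk[ok] - 1) * d[1] * d[2] + (jj[ok] - 1) * d[1] + ii[ok]
  occ[ok] <- mask$occupancy[lin]
  mask3d(array(occ, d), sp, org)
}

#' Nearest-neighbor resampling of a mask to a new spacing
#'
#' Contours are conformed to the canonical 1 mm isotropic grid with
#' nearest-neighbor interpolation (the interpolation appropriate for binary
#' occupancy; spline interpolation is only ever applied to gray-level
#' images, which this package does not consume).
#'
#' @param mask A [mask3d].
#' @param target_spacing Positive spacing in mm (scalar or length 3).
#' @return A [mask3d] at the target spacing covering the same physical
#'   extent.
#' @export
resample_mask <- function(mask, target_spacing = 1) {
  stopifnot(is_mask3d(mask))
  tg <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(tg)) || any(tg <= 0)) {
    stop_ranobm("target spacing must be strictly positive",
                "ranobm_invalid_value")
  }
  if (isTRUE(all.equal(tg, mask$spacing))) return(mask)
  d <- dim(mask$occupancy); sp <- mask$spacing; org <- mask$origin
  n_out <- pmax(1L, as.integer(round(d * sp / tg)))
  ix <- lapply(1:3, function(a) {
    p <- org[a] + (seq_len(n_out[a]) - 1) * tg[a]
    i <- round((p - org[a]) / sp[a]) + 1
    ifelse(i >= 1 & i <= d[a], i, NA_integer_)
  })
  occ <- array(0L, n_out)
  val <- mask$occupancy[
    cbind(rep(ix[[1]], times = n_out[2] * n_out[3]),
          rep(rep(ix[[2]], each = n_out[1]), times = n_out[3]),
          rep(ix[[3]], each = n_out[1] * n_out[2]))
  ]
  occ[] <- ifelse(is.na(val), 0L, val)
  mask3d(occ, tg, org)
}
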