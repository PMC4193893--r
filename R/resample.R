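#' Resample a volume onto a reference grid under a rigid transform
#'
#' The transform maps moving-volume world coordinates into reference world
#' coordinates; the output shares the reference grid exactly, so slice `j`
#' of the output aligns with slice `j` of the reference. Intensities are
#' interpolated with a cubic (Catmull-Rom) kernel by default, mirroring
#' spline resampling; masks should use `order = 0`. Out-of-field voxels
#' take `fill` (default: the minimum intensity of the moving volume, i.e.
#' air in CT-like data).
#'
#' @param moving a `scan_volume` to resample.
#' @param transform `rigid_transform` mapping moving world to reference
#'   world coordinates.
#' @param reference a `scan_volume` defining the output grid.
#' @param order interpolation order: 0 (nearest), 1 (trilinear) or 3
#'   (cubic).
#' @param fill background value for voxels outside the moving field of
#'   view.
#' @return A `scan_volume` on the reference grid.
#' @export
resample_to_reference <- function(moving, transform, reference, order = 3,
                                  fill = NULL) {
  stopifnot(inherits(moving, "scan_volume"), inherits(reference, "scan_volume"),
            order %in% c(0, 1, 3))
  if (abs(det(transform$rotation)) < 1e-8)
    stop("transform is not invertible")
  if (is.null(fill)) fill <- min(moving$data)
  inv <- invert_transform(transform)
  d <- dim(reference$data)
  out <- array(fill, d)
  # process in z-slabs to bound memory
  slab <- max(1L, as.integer(2e6 / (d[1] * d[2])))
  ij <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1)))
  for (k0 in seq(0, d[3] - 1, by = slab)) {
    ks <- k0:min(d[3] - 1, k0 + slab - 1)
    idx <- cbind(ij[rep(seq_len(nrow(ij)), length(ks)), , drop = FALSE],
                 k = rep(ks, each = nrow(ij)))
    w_ref <- voxel_to_world(reference, idx)
    w_mov <- transform_points(inv, w_ref)
    v_mov <- world_to_voxel(moving, w_mov)
    vals <- cpp_sample_volume(as.numeric(moving$data), dim(moving$data),
                              v_mov, as.integer(order), fill)
    out[, , ks + 1] <- array(vals, c(d[1], d[2], length(ks)))
  }
  scan_volume(out, reference$spacing, reference$origin, reference$orientation,
              gantry_tilt_deg = reference$gantry_tilt_deg)
}

#' Resample a binary mask onto a reference grid
#'
#' Binarity-preserving resampling. The default interpolates the 0/1
#' indicator trilinearly and thresholds at 0.5, which reproduces the
#' mask boundary with sub-voxel accuracy (half-voxel jitter of
#' nearest-neighbour transport would otherwise dominate small volume
#' differences); `order = 0` gives plain nearest-neighbour.
#'
#' @param mask a `binary_mask`.
#' @param transform `rigid_transform`, moving world to reference world.
#' @param reference a `scan_volume` or `binary_mask` giving the grid.
#' @param order 1 (trilinear indicator, default) or 0 (nearest).
#' @return A `binary_mask` on the reference grid.
#' @export
resample_mask <- function(mask, transform, reference, order = 1) {
  stopifnot(order %in% c(0, 1))
  v <- scan_volume(array(as.numeric(mask$values), dim(mask$values)),
                   mask$spacing, mask$origin, mask$orientation)
  ref <- if (inherits(reference, "binary_mask")) {
    scan_volume(array(0, dim(reference$values)), reference$spacing,
                reference$origin, reference$orientation)
  } else reference
  r <- resample_to_reference(v, transform, ref, order = order, fill = 0)
  binary_mask(r$data > 0.5, r, role = mask$role)
}

#' Correct gantry tilt by in-plane slice shearing
#'
#' CT acquired with a tilted gantry stores slice stacks sheared along the
#' anterior-posterior axis: slice `k` is displaced in-plane by
#' `k * slice_spacing * tan(tilt)`. This undoes the shear by translating
#' each slice back (linear interpolation) and sets the tilt to zero, so
#' the volume can be treated as an orthogonal stack before registration.
#'
#' @param v a `scan_volume` with `gantry_tilt_deg` set.
#' @param axis in-plane axis of the shear (1 = x, 2 = y); gantry tilt
#'   about the patient's left-right axis shears along y (the default).
#' @return A `scan_volume` with `gantry_tilt_deg = 0`.
#' @export
correct_gantry_tilt <- function(v, axis = 2) {
  stopifnot(inherits(v, "scan_volume"), axis %in% c(1, 2))
  tilt <- v$gantry_tilt_deg
  if (abs(tilt) >= 90)
    stop("gantry tilt magnitude must be below 90 degrees")
  if (tilt == 0) return(v)
  d <- dim(v$data)
  fill <- min(v$data)
  out <- array(fill, d)
  dz <- v$spacing[3]
  shift_mm <- (seq_len(d[3]) - 1) * dz * tan(tilt * pi / 180)
  ij <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1)))
  for (k in seq_len(d[3])) {
    idx <- cbind(ij, k = k - 1)
    idx[, axis] <- idx[, axis] + shift_mm[k] / v$spacing[axis]
    vals <- cpp_sample_volume(as.numeric(v$data), d, idx, 1L, fill)
    out[, , k] <- matrix(vals, d[1], d[2])
  }
  scan_volume(out, v$spacing, v$origin, v$orientation, gantry_tilt_deg = 0)
}
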