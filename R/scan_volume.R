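#' 3-D CT-like scan volume
#'
#' Container for a scalar intensity grid with physical geometry. World
#' coordinates follow the voxel-centre convention with 0-based indices:
#' `world(i,j,k) = origin + orientation %*% (spacing * c(i,j,k))`.
#'
#' @param data 3-D numeric array of intensities (HU-like).
#' @param spacing voxel spacing in mm (length 3, strictly positive).
#' @param origin world position of voxel (0,0,0) in mm.
#' @param orientation 3x3 orthonormal direction matrix.
#' @param gantry_tilt_deg gantry tilt in degrees (0 when absent).
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(data, spacing, origin = c(0, 0, 0),
                        orientation = diag(3), gantry_tilt_deg = 0) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  stopifnot(length(origin) == 3, all(dim(orientation) == c(3, 3)))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation,
                 gantry_tilt_deg = as.numeric(gantry_tilt_deg)),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  cat("scan_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing (", paste(x$spacing, collapse = ", "), ") mm")
  if (x$gantry_tilt_deg != 0)
    cat(", gantry tilt", x$gantry_tilt_deg, "deg")
  cat("\n")
  invisible(x)
}

#' @export
dim.scan_volume <- function(x) dim(x$data)

#' Map 0-based voxel indices to world mm coordinates
#' @param v a `scan_volume` (or `binary_mask`).
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(v, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, 1, 3)
  sweep(sweep(idx, 2, v$spacing, "*") %*% t(v$orientation), 2, v$origin, "+")
}

#' Map world mm coordinates to continuous 0-based voxel indices
#' @param v a `scan_volume` (or `binary_mask`).
#' @param pts n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(v, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  sweep(sweep(pts, 2, v$origin, "-") %*% v$orientation, 2, v$spacing, "/")
}

#' Voxel volume in mm^3
#' @param v a `scan_volume` or `binary_mask`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(v) prod(v$spacing)

#' Binary mask on a scan-volume geometry
#'
#' @param values 3-D logical array.
#' @param geometry a `scan_volume` (or another mask) providing the grid.
#' @param role what the mask labels, `"skull"` or `"brain"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, geometry, role = c("brain", "skull")) {
  role <- match.arg(role)
  values <- as.array(values)
  storage.mode(values) <- "logical"
  stopifnot(all(dim(values) == dim(geometry$data) | is.null(geometry$data)))
  structure(list(values = values, spacing = geometry$spacing,
                 origin = geometry$origin, orientation = geometry$orientation,
                 role = role),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask (", x$role, "): ", sum(x$values), " voxels, ",
      format(sum(x$values) * voxel_volume(x) / 1000, digits = 4), " ml\n",
      sep = "")
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' Check two volumes/masks share the same grid
#' @param a,b `scan_volume` or `binary_mask` objects.
#' @param tol geometric tolerance in mm.
#' @return TRUE or FALSE.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "binary_mask")) dim(a$values) else dim(a$data)
  db <- if (inherits(b, "binary_mask")) dim(b$values) else dim(b$data)
  all(da == db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' Mask volume in millilitres
#' @param mask a `binary_mask`.
#' @return Volume of the TRUE voxels in ml.
#' @export
mask_volume_ml <- function(mask) sum(mask$values) * voxel_volume(mask) / 1000

# grid must be axis-aligned (orientation a signed permutation close to
# identity) for slice-wise operations
assert_axis_aligned <- function(v) {
  if (max(abs(v$orientation - diag(3))) > 1e-6)
    stop("operation requires an axis-aligned (identity orientation) grid; ",
         "resample the volume first")
  invisible(TRUE)
}

# world coordinates of the grid axes (voxel centres), axis-aligned grids
axis_coords <- function(v) {
  d <- if (inherits(v, "binary_mask")) dim(v$values) else dim(v$data)
  list(x = v$origin[1] + (seq_len(d[1]) - 1) * v$spacing[1],
       y = v$origin[2] + (seq_len(d[2]) - 1) * v$spacing[2],
       z = v$origin[3] + (seq_len(d[3]) - 1) * v$spacing[3])
}
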