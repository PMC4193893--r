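#' Window/level intensity mapping
#'
#' Linearly rescales intensities so that
#' `[level - window/2, level + window/2]` spans `out_range`, clipping
#' outside. Used to accentuate the brain edge before region merging.
#'
#' @param v a `scan_volume`.
#' @param window window width (> 0), HU-like.
#' @param level window centre, HU-like.
#' @param out_range output intensity range (default 0..255).
#' @return A `scan_volume` with remapped intensities.
#' @export
window_level <- function(v, window, level, out_range = c(0, 255)) {
  stopifnot(inherits(v, "scan_volume"))
  if (window <= 0) stop("window must be > 0")
  lo <- level - window / 2
  x <- (v$data - lo) / window
  x[x < 0] <- 0
  x[x > 1] <- 1
  scan_volume(out_range[1] + x * diff(out_range), v$spacing, v$origin,
              v$orientation, v$gantry_tilt_deg)
}

#' Statistical region merging of a 2-D slice
#'
#' Region-growing segmentation after Nock & Nielsen: 4-neighbour pixel
#' pairs are visited in order of absolute intensity difference and their
#' regions merged while the difference of region means stays below a
#' statistical bound controlled by the granularity `Q` (larger `Q`, finer
#' segmentation).
#'
#' @param img numeric matrix (one slice).
#' @param Q merging granularity, `>= 1`.
#' @return Integer matrix of per-pixel region labels (1-based).
#' @export
statistical_region_merging <- function(img, Q = 25) {
  stopifnot(is.matrix(img))
  if (Q < 1) stop("Q must be >= 1")
  cpp_srm(img, Q)
}

#' Keep regions whose mean intensity lies in a band
#'
#' @param labels integer label matrix from
#'   [statistical_region_merging()].
#' @param img the intensity matrix the means are computed on (same shape).
#' @param band length-2 numeric: regions with mean in `[band[1], band[2]]`
#'   are kept.
#' @return Logical matrix; attribute `empty` is TRUE when no region
#'   survives (the slice should then be excluded and logged).
#' @export
threshold_regions <- function(labels, img, band) {
  stopifnot(all(dim(labels) == dim(img)), length(band) == 2)
  means <- rowsum(as.numeric(img), as.integer(labels))
  counts <- tabulate(as.integer(labels))
  means <- means[, 1] / counts
  keep_ids <- which(means >= band[1] & means <= band[2])
  out <- matrix(labels %in% keep_ids, nrow(labels), ncol(labels))
  attr(out, "empty") <- length(keep_ids) == 0
  out
}

#' Clean a slice mask: fill holes and regularise the contour
#'
#' Produces one simply-connected region per connected brain area:
#' interior holes are filled and the boundary is smoothed by a short
#' morphological curve evolution (closing then opening with a small disc)
#' that pulls the contour onto the nearest coherent edge while leaving an
#' already-clean convex mask unchanged to within a voxel. If the
#' regularisation collapses the region, the hole-filled input is returned
#' and the fallback is flagged.
#'
#' @param mask_slice logical matrix.
#' @param img optional intensity matrix (unused by the morphological
#'   evolution; kept for interface compatibility with edge-driven
#'   variants).
#' @param radius structuring-disc radius in pixels.
#' @return Logical matrix; attribute `fallback` is TRUE when the
#'   morphological evolution collapsed and hole filling alone was used.
#' @export
active_contour_cleanup <- function(mask_slice, img = NULL, radius = 2) {
  stopifnot(is.logical(mask_slice) || all(mask_slice %in% c(0, 1)))
  m <- matrix(as.numeric(mask_slice), nrow(mask_slice), ncol(mask_slice))
  if (!any(m > 0)) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    attr(out, "fallback") <- FALSE
    return(out)
  }
  filled <- EBImage::fillHull(EBImage::Image(m))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  # opening regularises the contour without ever growing it (a closing
  # would pad concave staircase corners and bias outward measurements)
  smoothed <- EBImage::opening(filled, brush)
  # the evolution must stay within one voxel of the hole-filled input
  box3 <- EBImage::makeBrush(3, shape = "box")
  grown <- EBImage::imageData(EBImage::dilate(filled, box3)) > 0.5
  core <- EBImage::imageData(EBImage::erode(filled, box3)) > 0.5
  sm <- (EBImage::imageData(smoothed) > 0.5 & grown) | core
  fallback <- !any(sm)
  out <- if (fallback) EBImage::imageData(filled) > 0.5 else sm
  out <- matrix(out, nrow(m), ncol(m))
  attr(out, "fallback") <- fallback
  out
}

#' Extract per-slice brain edge coordinates
#'
#' Traces the boundary of the mask on every slice as ordered, closed
#' polygons in world mm, with sub-voxel positions obtained by linear
#' interpolation of the (lightly smoothed) mask at the 0.5 level.
#' Without smoothing the 0.5 contour of a binary grid is a staircase
#' whose half-voxel teeth bias any maximum taken along the edge; a
#' sub-voxel Gaussian recovers a smooth boundary through the staircase.
#' Empty slices are omitted.
#'
#' @param mask a `binary_mask` on an axis-aligned grid.
#' @param sigma in-plane smoothing before contouring, in voxels
#'   (0 disables it).
#' @return A list of edge curves, each a list with `slice` (1-based z
#'   index), `z` (slice world z in mm) and `points` (closed n x 2 matrix
#'   of in-plane mm coordinates).
#' @export
extract_edge <- function(mask, sigma = 0.8) {
  stopifnot(inherits(mask, "binary_mask"))
  assert_axis_aligned(mask)
  ax <- axis_coords(mask)
  out <- list()
  for (k in seq_len(dim(mask$values)[3])) {
    m <- mask$values[, , k]
    if (!any(m)) next
    sl <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (sigma > 0)
      sl <- matrix(cpp_smooth3(as.numeric(sl), c(dim(sl), 1L),
                               c(sigma, sigma, 0)), nrow(sl), ncol(sl))
    cl <- contourLines(ax$x, ax$y, sl,
                       levels = 0.5)
    for (cc in cl) {
      p <- cbind(cc$x, cc$y)
      if (nrow(p) < 3) next
      if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
      out[[length(out) + 1]] <- list(slice = k, z = ax$z[k], points = p)
    }
  }
  out
}

# shoelace area of a closed polygon
polygon_area <- function(p) {
  n <- nrow(p)
  abs(sum(p[-n, 1] * p[-1, 2] - p[-1, 1] * p[-n, 2])) / 2
}

# fill interior cavities of a 3-D logical array (background connected to
# the border stays background)
fill_holes_3d <- function(values) {
  bg <- !values
  lab <- cpp_label3d(bg, dim(bg))
  d <- dim(values)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  values | (bg & !(lab %in% border_labels))
}

#' Pre-operative brain mask from the inner table of the skull
#'
#' Under raised intracranial pressure the brain is pressed against the
#' inner table, so the pre-op brain surface is taken as the interior
#' boundary of the skull: the mask is the cavity enclosed by the skull
#' shell (largest interior component).
#'
#' @param skull a `binary_mask` with role `"skull"`.
#' @return A `binary_mask` with role `"brain"`.
#' @export
brain_from_inner_table <- function(skull) {
  stopifnot(inherits(skull, "binary_mask"))
  cavity <- fill_holes_3d(skull$values) & !skull$values
  if (!any(cavity))
    stop("skull mask encloses no cavity; cannot derive the pre-op brain")
  lab <- cpp_label3d(cavity, dim(cavity))
  keep <- which.max(tabulate(lab[lab > 0L]))
  binary_mask(array(lab == keep, dim(cavity)), skull, role = "brain")
}

#' Segment the brain from a (post-operative) volume
#'
#' The slice-wise chain used throughout: window/level to accentuate the
#' brain edge, statistical region merging, retention of regions whose
#' mean intensity lies in the brain band, and morphological contour
#' cleanup. Slices where no region survives are excluded and counted.
#' The stacked mask is reduced to its largest 3-D component and interior
#' cavities are filled.
#'
#' @param v a `scan_volume`.
#' @param config parameter list, see [default_config()].
#' @return A `binary_mask` with role `"brain"`; attribute
#'   `empty_slices` counts excluded slices.
#' @export
segment_brain <- function(v, config = default_config()) {
  stopifnot(inherits(v, "scan_volume"))
  assert_axis_aligned(v)
  wl <- window_level(v, config$wl_window, config$wl_level)
  d <- dim(v$data)
  mask <- array(FALSE, d)
  empty <- 0L
  for (k in seq_len(d[3])) {
    sl <- wl$data[, , k]
    if (diff(range(sl)) < 1e-9) { empty <- empty + 1L; next }
    labs <- statistical_region_merging(sl, config$srm_Q)
    kept <- threshold_regions(labs, v$data[, , k], config$brain_band)
    if (attr(kept, "empty")) { empty <- empty + 1L; next }
    mask[, , k] <- active_contour_cleanup(kept, sl,
                                          radius = config$contour_radius)
  }
  if (!any(mask)) stop("brain segmentation produced an empty mask")
  lab <- cpp_label3d(mask, d)
  keep <- which.max(tabulate(lab[lab > 0L]))
  out <- binary_mask(fill_holes_3d(array(lab == keep, d)), v, role = "brain")
  attr(out, "empty_slices") <- empty
  out
}

#' Default pipeline parameters
#'
#' Central place for the tunable parameters of the measurement chain.
#' `skull_threshold = NULL` selects the bone threshold per volume from
#' the intensity modes. The window/level and brain band are in HU;
#' defaults are calibrated on the phantoms and bracket soft tissue while
#' excluding bone and air.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(skull_threshold = NULL,
       wl_window = 400,       # HU width accentuating the brain edge
       wl_level = 40,         # HU centre near brain parenchyma
       srm_Q = 25,            # SRM granularity
       brain_band = c(-150, 250),  # HU band of regions kept as brain
       contour_radius = 2,    # px, morphological cleanup disc
       station_spacing = NULL,  # mm, defaults to in-plane voxel spacing
       interp_order = 3)      # resampling order for intensities
}
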