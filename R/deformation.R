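#' Locate the craniectomy baseline from registered skull masks
#'
#' The aperture is the bone present pre-operatively but absent
#' post-operatively (`pre & !post`, largest component). Its rim -- the
#' boundary of the aperture region against the surviving skull -- is
#' extracted as 3-D world coordinates, a baseline plane is fitted to the
#' rim by least squares, and the outward unit normal (pointing away from
#' the brain) is recorded. Height and width are the rim's maximal
#' extents along the plane's two principal in-plane axes; per-slice
#' chords of the opening are retained for the Flint measure.
#'
#' @param pre_skull,post_skull `binary_mask` objects on the same grid
#'   (pre already registered to the post grid).
#' @param min_voxels smallest aperture accepted as a craniectomy.
#' @return A `craniectomy_baseline`: `rim_points` (n x 3 mm),
#'   `plane_point`, `plane_normal` (outward, unit), `height`, `width`
#'   (mm), `per_slice` (data frame of aperture chord endpoints per
#'   slice), `centroid` (rim centroid, mm).
#' @export
locate_baseline <- function(pre_skull, post_skull, min_voxels = 50) {
  stopifnot(inherits(pre_skull, "binary_mask"),
            inherits(post_skull, "binary_mask"))
  if (!same_grid(pre_skull, post_skull))
    stop("skull masks must share a registered grid")
  assert_axis_aligned(pre_skull)
  ap <- pre_skull$values & !post_skull$values
  if (!any(ap)) stop("no craniectomy: pre-op and post-op skulls agree")
  lab <- cpp_label3d(ap, dim(ap))
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_voxels)
    stop("no craniectomy: largest removed-bone region has ",
         max(sizes), " voxels")
  ap <- array(lab == which.max(sizes), dim(ap))

  # rim: midpoints of aperture voxel / surviving-skull voxel face pairs,
  # placing the rim on the opening wall at sub-voxel accuracy
  d <- dim(ap)
  post <- post_skull$values
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  rim_list <- list()
  for (s in shifts) {
    pair <- array(FALSE, d)
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    for (a in 1:3) {
      if (s[a] == 1) { src[[a]] <- 1:(d[a] - 1); dst[[a]] <- 2:d[a] }
      if (s[a] == -1) { src[[a]] <- 2:d[a]; dst[[a]] <- 1:(d[a] - 1) }
    }
    pair[src[[1]], src[[2]], src[[3]]] <-
      ap[src[[1]], src[[2]], src[[3]]] & post[dst[[1]], dst[[2]], dst[[3]]]
    idx <- which(pair)
    if (length(idx))
      rim_list[[length(rim_list) + 1]] <-
        sweep(arrayInd(idx, d) - 1, 2, s / 2, "+")
  }
  if (!length(rim_list)) stop("aperture rim could not be traced")
  rim_idx_frac <- do.call(rbind, rim_list)
  if (nrow(rim_idx_frac) < 10)
    stop("aperture rim could not be traced (fewer than 10 rim points)")
  rim <- voxel_to_world(pre_skull, rim_idx_frac)

  ctr <- colMeans(rim)
  sv <- svd(sweep(rim, 2, ctr, "-"))
  normal <- sv$v[, 3]
  # orient away from the brain: away from the skull centroid
  skull_ctr <- colMeans(voxel_to_world(
    pre_skull, arrayInd(which(pre_skull$values), d) - 1))
  if (sum((ctr - skull_ctr) * normal) < 0) normal <- -normal
  e1 <- sv$v[, 1]
  e2 <- sv$v[, 2]
  # name the more vertical in-plane axis "height"
  if (abs(e2[3]) > abs(e1[3])) { tmp <- e1; e1 <- e2; e2 <- tmp }
  local <- sweep(rim, 2, ctr, "-")
  height <- diff(range(local %*% e1))
  width <- diff(range(local %*% e2))

  # per-slice chord of the opening: the two most separated rim points
  slice_of <- as.integer(round(rim_idx_frac[, 3])) + 1L
  ks <- sort(unique(slice_of))
  seg <- do.call(rbind, lapply(ks, function(k) {
    pk <- rim[slice_of == k, , drop = FALSE]
    if (nrow(pk) < 2) return(NULL)
    pr <- prcomp(pk[, 1:2], center = TRUE)
    t1 <- pk[which.min(pr$x[, 1]), ]
    t2 <- pk[which.max(pr$x[, 1]), ]
    data.frame(slice = k, x1 = t1[1], y1 = t1[2], x2 = t2[1], y2 = t2[2],
               z = pre_skull$origin[3] + (k - 1) * pre_skull$spacing[3],
               chord = sqrt(sum((t1[1:2] - t2[1:2])^2)))
  }))
  structure(list(rim_points = rim, plane_point = ctr, plane_normal = normal,
                 height = height, width = width, per_slice = seg,
                 centroid = ctr, spacing = pre_skull$spacing),
            class = "craniectomy_baseline")
}

#' @export
print.craniectomy_baseline <- function(x, ...) {
  cat("craniectomy_baseline:", nrow(x$rim_points), "rim points, height",
      sprintf("%.1f", x$height), "mm, width", sprintf("%.1f", x$width),
      "mm, normal (", paste(sprintf("%.2f", x$plane_normal), collapse = ", "),
      ")\n")
  invisible(x)
}

# in-plane (xy) outward direction of the baseline on axial slices
inplane_normal <- function(baseline) {
  m <- baseline$plane_normal[1:2]
  if (sqrt(sum(m^2)) < 1e-6)
    stop("baseline normal is perpendicular to the slice plane; ",
         "slice-wise measures are undefined")
  m / sqrt(sum(m^2))
}

# all intersections of the line p(s) = origin + s * dir with the closed
# polygon `poly` (n x 2); returns the s values
ray_polygon_s <- function(origin, dir, poly) {
  n <- nrow(poly)
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]
  ey <- b[, 2] - a[, 2]
  # solve origin + s*dir = a + t*e, t in [0,1)
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  ok <- abs(den) > 1e-12
  if (!any(ok)) return(numeric(0))
  rx <- a[, 1] - origin[1]
  ry <- a[, 2] - origin[2]
  s <- (rx * (-ey) - ry * (-ex)) / den
  t <- (dir[1] * ry - dir[2] * rx) / den
  s[ok & t >= 0 & t < 1]
}

#' Flint displacement from the post-operative scan alone
#'
#' The classical single-slice measure: on the slice where the craniectomy
#' chord is longest, the maximum perpendicular distance from the chord to
#' the post-operative brain edge on the herniation side. Because it
#' ignores the pre-operative brain shape it overestimates the true
#' displacement, and it is sensitive to the baseline position for
#' bifrontal openings.
#'
#' @param post_edges edge curves from [extract_edge()] of the post-op
#'   brain mask.
#' @param baseline a `craniectomy_baseline`.
#' @return `y_flint` in mm (0 when no brain edge lies beyond the
#'   baseline), with attribute `slice`.
#' @export
flint_displacement <- function(post_edges, baseline) {
  stopifnot(inherits(baseline, "craniectomy_baseline"))
  seg <- baseline$per_slice
  if (is.null(seg) || nrow(seg) == 0) stop("baseline has no per-slice chords")
  row <- seg[which.max(seg$chord), ]
  m <- inplane_normal(baseline)
  a <- c(row$x1, row$y1)
  b <- c(row$x2, row$y2)
  dvec <- (b - a)
  L <- sqrt(sum(dvec^2))
  dvec <- dvec / L
  best <- 0
  for (e in post_edges) {
    if (e$slice != row$slice) next
    rel <- sweep(e$points, 2, a, "-")
    tt <- rel %*% dvec
    dd <- rel %*% m
    sel <- tt >= -5 & tt <= L + 5
    if (any(sel)) best <- max(best, max(dd[sel]))
  }
  structure(max(0, best), slice = row$slice)
}

#' Baseline-normal displacement field between pre- and post-op edges
#'
#' For each axial slice crossing the aperture, stations are laid along
#' the baseline chord at a regular spacing and a ray is cast from each
#' station along the outward in-plane baseline normal. `y_pre` and
#' `y_post` are the signed distances from the baseline to the outermost
#' crossing of the pre-op and post-op brain edges; the displacement is
#' their difference `dy = y_post - y_pre` at every station. Stations
#' with no crossing in either scan are excluded and counted. The maximum
#' `dy_max` is recorded with its station; ties are broken toward the
#' station nearest the aperture centroid.
#'
#' @param pre_edges,post_edges edge curves from [extract_edge()] on the
#'   same registered grid.
#' @param baseline a `craniectomy_baseline`.
#' @param station_spacing station spacing along the chord in mm;
#'   defaults to the in-plane voxel spacing.
#' @return A `displacement_field`: data frame `samples` with columns
#'   `slice`, `station` (mm along the chord), `x`, `y`, `z`, `y_pre`,
#'   `y_post`, `dy`; plus `dy_max`, `dy_max_at` (world mm), and
#'   `n_excluded`.
#' @export
displacement_field <- function(pre_edges, post_edges, baseline,
                               station_spacing = NULL) {
  stopifnot(inherits(baseline, "craniectomy_baseline"))
  if (is.null(station_spacing))
    station_spacing <- min(baseline$spacing[1:2])
  m <- inplane_normal(baseline)
  seg <- baseline$per_slice
  rows <- list()
  excluded <- 0L
  pre_by_slice <- split(pre_edges, vapply(pre_edges, `[[`, 1L, "slice"))
  post_by_slice <- split(post_edges, vapply(post_edges, `[[`, 1L, "slice"))
  for (r in seq_len(nrow(seg))) {
    sl <- seg$slice[r]
    pe <- pre_by_slice[[as.character(sl)]]
    qe <- post_by_slice[[as.character(sl)]]
    if (is.null(pe) || is.null(qe)) next
    a <- c(seg$x1[r], seg$y1[r])
    b <- c(seg$x2[r], seg$y2[r])
    L <- sqrt(sum((b - a)^2))
    if (L < station_spacing) next
    dvec <- (b - a) / L
    tvals <- seq(0, L, by = station_spacing)
    for (tv in tvals) {
      st <- a + tv * dvec
      s_pre <- unlist(lapply(pe, function(e) ray_polygon_s(st, m, e$points)))
      s_post <- unlist(lapply(qe, function(e) ray_polygon_s(st, m, e$points)))
      if (!length(s_pre) || !length(s_post)) {
        excluded <- excluded + 1L
        next
      }
      # outermost boundary crossing beyond the baseline
      y_pre <- max(s_pre)
      y_post <- max(s_post)
      rows[[length(rows) + 1]] <- data.frame(
        slice = sl, station = tv, x = st[1], y = st[2], z = seg$z[r],
        y_pre = y_pre, y_post = y_post, dy = y_post - y_pre)
    }
  }
  if (!length(rows))
    stop("no valid displacement stations; check registration and masks")
  samples <- do.call(rbind, rows)
  dmax <- max(samples$dy)
  cand <- which(samples$dy >= dmax - 1e-9)
  if (length(cand) > 1) {
    pc <- as.matrix(samples[cand, c("x", "y", "z")])
    dcen <- rowSums(sweep(pc, 2, baseline$centroid, "-")^2)
    cand <- cand[which.min(dcen)]
  } else cand <- cand[1]
  structure(list(samples = samples, dy_max = samples$dy[cand],
                 dy_max_at = as.numeric(samples[cand, c("x", "y", "z")]),
                 n_excluded = excluded),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("displacement_field:", nrow(x$samples), "stations, dy_max",
      sprintf("%.2f", x$dy_max), "mm,", x$n_excluded, "excluded\n")
  invisible(x)
}

#' Herniated volume from brain-mask differencing
#'
#' The pre/post difference of segmented brain-mask volumes. Negative
#' values are permitted but flagged: they signal segmentation or
#' registration problems (or genuine pre-op volume loss such as
#' haematoma evacuation).
#'
#' @param pre_brain,post_brain `binary_mask` objects on identical grids.
#' @return `dV` in ml; attribute `negative` flags `dV < 0`.
#' @export
herniated_volume <- function(pre_brain, post_brain) {
  stopifnot(inherits(pre_brain, "binary_mask"),
            inherits(post_brain, "binary_mask"))
  if (!same_grid(pre_brain, post_brain))
    stop("brain masks must share an identical grid")
  dv <- (sum(post_brain$values) - sum(pre_brain$values)) *
    voxel_volume(post_brain) / 1000
  structure(dv, negative = dv < 0)
}

#' Craniectomy area as height times width
#'
#' The simple rectangular estimate: the product of the maximal height
#' and width of the opening. It exceeds the inscribed-ellipse area
#' `pi * h * w / 4` by the constant factor `4 / pi` (about 1.27).
#'
#' @param baseline a `craniectomy_baseline`, or a numeric height in mm
#'   (in which case `width` must be given).
#' @param width opening width in mm when `baseline` is numeric.
#' @return Area in mm^2.
#' @export
area_height_width <- function(baseline, width = NULL) {
  if (is.numeric(baseline)) {
    stopifnot(!is.null(width), baseline > 0, width > 0)
    return(baseline * width)
  }
  stopifnot(inherits(baseline, "craniectomy_baseline"))
  baseline$height * baseline$width
}

# triangle areas, unit normals and centroids from an ntri x 9 matrix
mesh_triangles <- function(tri) {
  p1 <- tri[, 1:3, drop = FALSE]
  p2 <- tri[, 4:6, drop = FALSE]
  p3 <- tri[, 7:9, drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(cr^2))
  list(area = nn / 2, normal = cr / pmax(nn, 1e-12),
       centroid = (p1 + p2 + p3) / 3)
}

#' Craniectomy area from the skull surface mesh
#'
#' Triangulates the pre-operative skull iso-surface (marching tetrahedra
#' on a lightly smoothed mask) and measures the change in skull surface
#' area due to the opening: the area of the pre-op outer table over the
#' removed-bone footprint (`pre & !post`). Outer-table triangles are
#' identified by probing outward along the triangle normal against the
#' filled pre-op head. The estimate is flagged rather than rejected when
#' the mesh is degenerate -- on clinical data this estimator is known to
#' be unreliable in some cases.
#'
#' @param pre_skull,post_skull registered `binary_mask` objects.
#' @param sigma smoothing (in voxels along the finest axis) before
#'   iso-surfacing.
#' @return Area in mm^2; attribute `degenerate` flags an unusable result
#'   (no aperture or an empty mesh).
#' @export
area_mesh <- function(pre_skull, post_skull, sigma = 1.5) {
  stopifnot(inherits(pre_skull, "binary_mask"),
            inherits(post_skull, "binary_mask"))
  if (!same_grid(pre_skull, post_skull))
    stop("skull masks must share a registered grid")
  d <- dim(pre_skull$values)
  sp <- pre_skull$spacing
  ap <- array(as.numeric(pre_skull$values & !post_skull$values), d)
  if (sum(ap) == 0)
    return(structure(0, degenerate = TRUE))
  head_solid <- array(as.numeric(fill_holes_3d(pre_skull$values)), d)
  sm <- cpp_smooth3(as.numeric(pre_skull$values), d, sigma * min(sp) / sp)
  tri <- cpp_march_tets(as.numeric(sm), d, sp, 0.5)
  if (nrow(tri) == 0)
    return(structure(0, degenerate = TRUE))
  mt <- mesh_triangles(tri)
  step <- 2 * max(sp)
  # outer table: probing outward leaves the filled head
  vi_out <- sweep(mt$centroid + step * mt$normal, 2, sp, "/")
  outer <- cpp_sample_volume(head_solid, d, vi_out, 1L, 0) < 0.5
  # aperture footprint: probing just below the outer table must land in
  # removed bone; the smoothed indicator at the 0.5 level places the
  # footprint wall at sub-voxel accuracy
  sm_ap <- cpp_smooth3(ap, d, min(sp) / sp)
  vi_in <- sweep(mt$centroid - 0.5 * step * mt$normal, 2, sp, "/")
  in_ap <- cpp_sample_volume(sm_ap, d, vi_in, 1L, 0) > 0.5
  keep <- outer & in_ap
  res <- sum(mt$area[keep])
  structure(res, degenerate = sum(keep) == 0 || res <= 0)
}
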