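#' Suggest a skull threshold for a CT-like volume
#'
#' Picks the midpoint between the two upper intensity modes (soft tissue
#' and bone) by two-means clustering of the non-air voxels. Deterministic:
#' Lloyd iterations from quartile-based initial centres.
#'
#' @param v a `scan_volume`.
#' @param air_cutoff intensities at or below this are treated as air and
#'   ignored.
#' @return Threshold intensity (HU-like scalar).
#' @export
suggest_skull_threshold <- function(v, air_cutoff = -200) {
  x <- as.numeric(v$data)
  x <- x[x > air_cutoff]
  if (length(x) < 10) stop("volume contains almost no non-air voxels")
  if (length(x) > 2e5) x <- x[seq(1, length(x), length.out = 2e5)]
  c1 <- quantile(x, 0.25, names = FALSE)
  c2 <- quantile(x, 0.975, names = FALSE)
  for (it in 1:50) {
    mid <- (c1 + c2) / 2
    n1 <- mean(x[x <= mid])
    n2 <- mean(x[x > mid])
    if (!is.finite(n1) || !is.finite(n2)) break
    if (abs(n1 - c1) < 1e-9 && abs(n2 - c2) < 1e-9) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Threshold-isolate the skull
#'
#' Voxels at or above `threshold` form the candidate bone mask; the
#' largest 6-connected component is retained.
#'
#' @param v a `scan_volume`.
#' @param threshold HU-like threshold between brain and bone; `NULL`
#'   selects it automatically with [suggest_skull_threshold()].
#' @return A `binary_mask` with role `"skull"`.
#' @export
skull_mask <- function(v, threshold = NULL) {
  stopifnot(inherits(v, "scan_volume"))
  if (is.null(threshold)) threshold <- suggest_skull_threshold(v)
  m <- v$data >= threshold
  if (!any(m))
    stop("skull threshold ", format(threshold),
         " exceeds every intensity in the volume; check configuration")
  lab <- cpp_label3d(m, dim(m))
  keep <- which.max(tabulate(lab[lab > 0L]))
  binary_mask(array(lab == keep, dim(m)), v, role = "skull")
}

#' Signed distance to a mask boundary
#'
#' Euclidean distance in mm to the mask boundary, negative inside the
#' mask; anisotropic spacing is honoured.
#' @param mask a `binary_mask`.
#' @return Numeric array on the mask grid.
#' @export
signed_distance <- function(mask) {
  d_out <- cpp_edt(as.logical(mask$values), dim(mask$values), mask$spacing)
  d_in <- cpp_edt(!as.logical(mask$values), dim(mask$values), mask$spacing)
  array(d_out - d_in, dim(mask$values))
}

#' Rigidly register two skull masks
#'
#' Estimates the 6 degree-of-freedom world transform mapping the moving
#' skull onto the fixed skull. The cost is the mean squared difference
#' between Gaussian-smoothed mask indicator functions, evaluated at
#' fixed-grid points near the fixed skull surface with the moving field
#' sampled through the candidate transform (trilinear). Smoothing makes
#' the binary masks continuous, so the optimum is sub-voxel; sampling
#' only near the fixed surface, together with trimming the worst
#' residuals, keeps bone present in just one scan (e.g. the removed
#' craniectomy flap) from steering the fit. Optimised by Nelder-Mead
#' from a deterministic multi-start schedule (centroid alignment plus
#' rotational offsets).
#'
#' @param fixed_skull,moving_skull `binary_mask` objects (role skull).
#' @param sigma_mm Gaussian smoothing of the mask indicators, mm.
#' @param trim fraction of best-matching sample points kept in the cost.
#' @param n_points maximum number of fixed near-surface sample points.
#' @param starts list of length-6 numeric vectors (degrees x3, mm x3)
#'   added to the centroid-aligned initialisation.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `registration_result`: `transform` (moving world to fixed
#'   world), `final_metric` (squared indicator mismatch), `iterations`,
#'   `converged`, and `metric_trace` (best cost after each start,
#'   non-increasing).
#' @export
rigid_register <- function(fixed_skull, moving_skull, sigma_mm = 3,
                           trim = 0.95, n_points = 6000,
                           starts = list(c(0, 0, 0, 0, 0, 0),
                                         c(0, 0, 8, 0, 0, 0),
                                         c(0, 0, -8, 0, 0, 0),
                                         c(8, 0, 0, 0, 0, 0),
                                         c(0, 8, 0, 0, 0, 0)),
                           maxit = 600) {
  stopifnot(inherits(fixed_skull, "binary_mask"),
            inherits(moving_skull, "binary_mask"))
  if (!any(fixed_skull$values) || !any(moving_skull$values))
    stop("both skull masks must be non-empty")

  dfix <- dim(fixed_skull$values)
  dmov <- dim(moving_skull$values)
  sm_fix <- cpp_smooth3(as.numeric(fixed_skull$values), dfix,
                        sigma_mm / fixed_skull$spacing)
  sm_mov <- cpp_smooth3(as.numeric(moving_skull$values), dmov,
                        sigma_mm / moving_skull$spacing)

  near <- which(sm_fix > 0.02 & sm_fix < 0.98)
  if (length(near) > n_points)
    near <- near[seq(1, length(near), length.out = n_points)]
  pts <- voxel_to_world(fixed_skull, arrayInd(near, dfix) - 1)
  fvals <- sm_fix[near]

  c_mov <- colMeans(voxel_to_world(
    moving_skull, arrayInd(which(moving_skull$values), dmov) - 1))
  c_fix <- colMeans(voxel_to_world(
    fixed_skull, arrayInd(which(fixed_skull$values), dfix) - 1))
  t0 <- c_fix - c_mov

  par_to_transform <- function(p) {
    rigid_from_euler(p[1:3], center = c_mov, translation = t0 + p[4:6])
  }
  nkeep <- max(1L, floor(trim * length(fvals)))
  cost <- function(p) {
    inv <- invert_transform(par_to_transform(p))
    vi <- world_to_voxel(moving_skull, transform_points(inv, pts))
    mv <- cpp_sample_volume(sm_mov, dmov, vi, 1L, 0)
    mean(sort.int((fvals - mv)^2, method = "quick")[seq_len(nkeep)])
  }

  best <- NULL
  trace_best <- numeric(0)
  total_iter <- 0L
  for (si in seq_along(starts)) {
    fit <- optim(starts[[si]], cost, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    total_iter <- total_iter + fit$counts[1]
    if (is.null(best) || fit$value < best$value) best <- fit
    trace_best <- c(trace_best, if (length(trace_best))
      min(tail(trace_best, 1), fit$value) else fit$value)
  }
  # polish the winning start until the simplex collapses
  for (rep in 1:3) {
    fit <- optim(best$par, cost, method = "Nelder-Mead",
                 control = list(maxit = 4 * maxit, reltol = 1e-13))
    total_iter <- total_iter + fit$counts[1]
    if (fit$value <= best$value) best <- fit
    trace_best <- c(trace_best, min(tail(trace_best, 1), best$value))
  }

  structure(list(transform = par_to_transform(best$par),
                 final_metric = best$value,
                 iterations = as.integer(total_iter),
                 converged = best$convergence == 0,
                 metric_trace = trace_best),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result: metric", format(x$final_metric, digits = 4),
      "mm^2,", x$iterations, "evaluations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$transform)
  invisible(x)
}
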