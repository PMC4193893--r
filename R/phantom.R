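#' Specification of a synthetic craniectomy head phantom
#'
#' Defines an ellipsoidal skull shell filled by brain, an elliptical
#' craniectomy aperture with a smooth outward herniation of known height,
#' plus acquisition nuisances (noise, rigid pre/post misalignment, gantry
#' tilt). Every derived quantity the measurement chain should recover is
#' known analytically, so the phantom provides ground truth for the whole
#' pipeline.
#'
#' The pre-operative brain fills the skull to the inner table when
#' `brain_margin = 0` (the usual situation in raised intracranial
#' pressure, and the assumption under which the inner table stands in for
#' the pre-op brain surface). The post-operative volume removes the
#' aperture from the shell and displaces the brain boundary outward along
#' the aperture axis by a parabolic or spherical-cap profile peaking at
#' `bulge_height` in the aperture centre.
#'
#' @param skull_outer_radius base outer radius of the skull in mm; the
#'   shell is an ellipsoid with semi-axes `skull_outer_radius * axis_ratios`.
#' @param axis_ratios semi-axis ratios (x lateral, y anterior-posterior,
#'   z vertical).
#' @param skull_thickness shell thickness in mm (> 0).
#' @param brain_margin gap between inner table and brain surface in mm
#'   (normally 0).
#' @param aperture_location `"bifrontal"` (anterior, across the midline)
#'   or `"unilateral"` (one lateral convexity).
#' @param aperture_height,aperture_width aperture extents in mm; a
#'   circular opening of radius r has height = width = 2r.
#' @param bulge_height ground-truth maximum displacement in mm.
#' @param bulge_profile `"parabolic"` or `"spherical_cap"`.
#' @param intensity_skull,intensity_brain,intensity_background HU-like
#'   intensities; must satisfy skull > brain > background.
#' @param noise_sd additive Gaussian noise standard deviation (HU-like).
#' @param misalignment `rigid_transform` applied to the pre-op volume
#'   (the mapping registration should recover, pre world to post world).
#' @param gantry_tilt_deg gantry tilt applied to the post-op volume.
#' @param voxel_spacing mm triple; the anisotropic default emulates the
#'   thick-slice CT typical of emergency head imaging.
#' @param grid_shape voxel triple, or NULL to fit the head automatically.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(skull_outer_radius = 72,
                         axis_ratios = c(1, 1.25, 0.9),
                         skull_thickness = 6,
                         brain_margin = 0,
                         aperture_location = c("unilateral", "bifrontal"),
                         aperture_height = 70,
                         aperture_width = 70,
                         bulge_height = 25,
                         bulge_profile = c("parabolic", "spherical_cap"),
                         intensity_skull = 700,
                         intensity_brain = 40,
                         intensity_background = -1000,
                         noise_sd = 15,
                         misalignment = rigid_transform(),
                         gantry_tilt_deg = 0,
                         voxel_spacing = c(0.5, 0.5, 5),
                         grid_shape = NULL,
                         seed = 1L) {
  aperture_location <- match.arg(aperture_location)
  bulge_profile <- match.arg(bulge_profile)
  if (skull_thickness <= 0) stop("skull_thickness must be > 0")
  if (bulge_height < 0) stop("bulge_height must be >= 0")
  if (brain_margin < 0) stop("brain_margin must be >= 0")
  if (aperture_height <= 0 || aperture_width <= 0)
    stop("aperture dimensions must be positive")
  if (!(intensity_skull > intensity_brain &&
        intensity_brain > intensity_background))
    stop("intensities must satisfy skull > brain > background")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(misalignment, "rigid_transform"))
  spec <- structure(list(
    skull_outer_radius = skull_outer_radius, axis_ratios = axis_ratios,
    skull_thickness = skull_thickness, brain_margin = brain_margin,
    aperture_location = aperture_location,
    aperture_height = aperture_height, aperture_width = aperture_width,
    bulge_height = bulge_height, bulge_profile = bulge_profile,
    intensity_skull = intensity_skull, intensity_brain = intensity_brain,
    intensity_background = intensity_background, noise_sd = noise_sd,
    misalignment = misalignment, gantry_tilt_deg = gantry_tilt_deg,
    voxel_spacing = as.numeric(voxel_spacing), grid_shape = grid_shape,
    seed = as.integer(seed)), class = "phantom_spec")
  # geometric validity: the aperture rim must lie on the skull
  tr <- phantom_geometry(spec)
  if (is.null(tr)) stop("aperture larger than the skull extents")
  spec
}

# internal geometry shared by the generator and the truth manifest.
# Returns NULL when the aperture does not fit on the shell.
phantom_geometry <- function(spec) {
  radii_out <- spec$skull_outer_radius * spec$axis_ratios
  radii_in <- radii_out - spec$skull_thickness
  radii_brain <- radii_in - spec$brain_margin
  if (any(radii_brain <= 0)) return(NULL)
  u <- if (spec$aperture_location == "unilateral") c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(0, 0, 1)                      # aperture height axis (vertical)
  e2 <- c(crossprod_3(u, e1))           # aperture width axis
  a <- spec$aperture_height / 2
  b <- spec$aperture_width / 2
  # rim on the shell mid-surface: solve quadratic along u for each angle
  radii_mid <- radii_out - spec$skull_thickness / 2
  phi <- seq(0, 2 * pi, length.out = 181L)[-181L]
  q <- outer(a * cos(phi), e1) + outer(b * sin(phi), e2)
  A <- sum((u / radii_mid)^2)
  B <- 2 * (q %*% (u / radii_mid^2))
  C <- rowSums(sweep(q, 2, radii_mid, "/")^2) - 1
  disc <- B^2 - 4 * A * C
  if (any(disc <= 0)) return(NULL)      # aperture wall misses the shell
  s <- (-B + sqrt(disc)) / (2 * A)
  if (any(s <= 0)) return(NULL)
  rim <- sweep(q, 2, u * 0, "+") + outer(as.numeric(s), u)
  list(radii_out = radii_out, radii_in = radii_in, radii_brain = radii_brain,
       u = u, e1 = e1, e2 = e2, a = a, b = b,
       rim_local = rim, baseline_offset = mean(s))
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# bulge displacement profile delta(nu) for normalised in-plane radius nu,
# returning mm of outward displacement along the aperture axis
bulge_profile_fun <- function(spec) {
  h <- spec$bulge_height
  if (h == 0) return(function(nu) rep(0, length(nu)))
  if (spec$bulge_profile == "parabolic") {
    function(nu) pmax(0, h * (1 - nu^2))
  } else {
    req <- sqrt(spec$aperture_height * spec$aperture_width) / 2
    Rc <- (req^2 + h^2) / (2 * h)
    function(nu) {
      d <- sqrt(pmax(0, Rc^2 - (nu * req)^2)) - (Rc - h)
      pmax(0, d)
    }
  }
}

#' Analytic herniated volume of a phantom bulge
#'
#' Closed-form integral of the bulge profile over the elliptical
#' aperture: `pi * a * b * h / 2` for the parabolic profile (semi-axes
#' a, b, peak h) and the spherical-cap volume for the cap profile.
#'
#' @param spec a [phantom_spec()].
#' @return Volume in mm^3.
#' @export
phantom_true_dV <- function(spec) {
  h <- spec$bulge_height
  ab <- (spec$aperture_height / 2) * (spec$aperture_width / 2)
  if (h == 0) return(0)
  if (spec$bulge_profile == "parabolic") {
    pi * ab * h / 2
  } else {
    req <- sqrt(ab)
    Rc <- (req^2 + h^2) / (2 * h)
    pi * h^2 * (Rc - h / 3)   # spherical cap; ab scaling cancels for req^2 = ab
  }
}

#' Generate a synthetic pre/post craniectomy volume pair
#'
#' Rasterises the phantom described by `spec` onto its voxel grid. The
#' pre-operative volume has an intact skull with the brain at the inner
#' table (misaligned by `spec$misalignment`); the post-operative volume
#' has the aperture removed and the brain boundary displaced outward by
#' the bulge profile, optionally acquired with gantry tilt. Identical
#' spec and seed give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pre` and `post` (`scan_volume`) and
#'   `truth`, a list holding `true_dy_max` (mm), `true_dV` (mm^3),
#'   `true_area` (mm^2), the planted `misalignment`, the analytic
#'   `baseline_plane` (point + outward unit normal), the rim coordinates
#'   and the masks' analytic parameters.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  if (is.null(geo)) stop("aperture larger than the skull extents")
  sp <- spec$voxel_spacing
  shape <- spec$grid_shape
  if (is.null(shape)) {
    ext <- 2 * geo$radii_out + 14
    ext <- ext + abs(geo$u) * (spec$bulge_height + 6)
    shape <- as.integer(ceiling(ext / sp))
  }
  centre <- (shape - 1) / 2 * sp       # head centre in world mm (origin 0)
  delta_fun <- bulge_profile_fun(spec)

  indicator <- function(pts) {
    # pts: world mm coords, n x 3. Returns list(brain, shell, post_brain,
    # post_shell) logicals evaluated in the canonical (post) frame.
    pc <- sweep(pts, 2, centre, "-")
    fo <- rowSums(sweep(pc, 2, geo$radii_out, "/")^2)
    fi <- rowSums(sweep(pc, 2, geo$radii_in, "/")^2)
    fb <- rowSums(sweep(pc, 2, geo$radii_brain, "/")^2)
    shell <- fo <= 1 & fi > 1
    brain <- fb <= 1
    w1 <- pc %*% geo$e1
    w2 <- pc %*% geo$e2
    du <- pc %*% geo$u
    nu2 <- (w1 / geo$a)^2 + (w2 / geo$b)^2
    incyl <- nu2 <= 1 & du > 0
    post_shell <- shell & !incyl
    # displaced brain: shear along u by delta(nu) inside the aperture
    delta <- delta_fun(sqrt(pmax(0, nu2)))
    moved <- incyl & delta > 0
    post_brain <- brain
    if (any(moved)) {
      src <- pts[moved, , drop = FALSE] - outer(delta[moved], geo$u)
      sc <- sweep(src, 2, centre, "-")
      post_brain[moved] <- brain[moved] |
        rowSums(sweep(sc, 2, geo$radii_brain, "/")^2) <= 1
    }
    list(brain = brain, shell = shell,
         post_brain = post_brain, post_shell = post_shell)
  }

  rasterise <- function(eval_at, post = TRUE) {
    vol <- array(0, shape)
    ij <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1)))
    slab <- max(1L, as.integer(2e6 / (shape[1] * shape[2])))
    for (k0 in seq(0, shape[3] - 1, by = slab)) {
      ks <- k0:min(shape[3] - 1, k0 + slab - 1)
      idx <- cbind(ij[rep(seq_len(nrow(ij)), length(ks)), , drop = FALSE],
                   k = rep(ks, each = nrow(ij)))
      pts <- sweep(idx, 2, sp, "*")     # origin 0, identity orientation
      pts <- eval_at(pts, idx)
      ind <- indicator(pts)
      if (post) {
        val <- ifelse(ind$post_shell, spec$intensity_skull,
                      ifelse(ind$post_brain, spec$intensity_brain,
                             spec$intensity_background))
      } else {
        val <- ifelse(ind$shell, spec$intensity_skull,
                      ifelse(ind$brain, spec$intensity_brain,
                             spec$intensity_background))
      }
      vol[, , ks + 1] <- array(val, c(shape[1], shape[2], length(ks)))
    }
    vol
  }

  # pre-op: intact head observed in a frame misaligned by T (pre -> post):
  # the voxel at world x holds the canonical head evaluated at T(x)
  mis <- spec$misalignment
  pre_arr <- rasterise(function(pts, idx) transform_points(mis, pts),
                       post = FALSE)
  # post-op: aperture + bulge; gantry tilt shears slice k by
  # -k * dz * tan(theta) along y at acquisition (correction undoes it)
  tilt <- spec$gantry_tilt_deg
  post_arr <- rasterise(function(pts, idx) {
    if (tilt != 0)
      pts[, 2] <- pts[, 2] - idx[, 3] * sp[3] * tan(tilt * pi / 180)
    pts
  }, post = TRUE)

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    pre_arr <- pre_arr + array(rnorm(length(pre_arr), 0, spec$noise_sd), shape)
    post_arr <- post_arr + array(rnorm(length(post_arr), 0, spec$noise_sd), shape)
  }

  pre <- scan_volume(pre_arr, sp, gantry_tilt_deg = 0)
  post <- scan_volume(post_arr, sp, gantry_tilt_deg = tilt)

  rim <- sweep(geo$rim_local, 2, centre, "+")
  truth <- list(
    true_dy_max = spec$bulge_height,
    true_dV = phantom_true_dV(spec),
    true_area = spec$aperture_height * spec$aperture_width,
    misalignment = mis,
    baseline_plane = list(point = centre + geo$baseline_offset * geo$u,
                          normal = geo$u),
    rim_points = rim,
    centre = centre,
    aperture_axis = geo$u,
    spec = spec)
  list(pre = pre, post = post, truth = truth)
}

#' Write a phantom case to disk
#'
#' Writes `pre.nii.gz`, `post.nii.gz` and a YAML truth manifest
#' `truth.yaml` (scalar ground truth and the planted misalignment as a
#' 4x4 affine) into `dir`.
#'
#' @param case a list from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$pre, file.path(dir, "pre.nii.gz"))
  write_volume(case$post, file.path(dir, "post.nii.gz"))
  tr <- case$truth
  yaml::write_yaml(list(
    true_dy_max = tr$true_dy_max,
    true_dV = tr$true_dV,
    true_area = tr$true_area,
    baseline_point = as.numeric(tr$baseline_plane$point),
    baseline_normal = as.numeric(tr$baseline_plane$normal),
    misalignment = as.numeric(as_affine_matrix(tr$misalignment)),
    aperture_location = tr$spec$aperture_location),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
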