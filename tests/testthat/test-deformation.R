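test_that("baseline location recovers the planted aperture plane and extents", {
  m <- ph_masks_uni()
  bl <- locate_baseline(m$pre_skull, m$post_skull)
  tru <- m$ph$truth
  # normal within 2 degrees of the planted aperture axis
  cosang <- abs(sum(bl$plane_normal * tru$baseline_plane$normal))
  expect_gt(cosang, cos(2 * pi / 180))
  # outward: points away from the head centre
  expect_gt(sum((bl$plane_point - tru$centre) * bl$plane_normal), 0)
  # height/width of the 70 mm circular opening within 2 voxel spacings
  sp <- m$pre_skull$spacing
  expect_lt(abs(bl$height - 70), 2 * max(sp))
  expect_lt(abs(bl$width - 70), 2 * max(sp))
  # rim points lie close to the fitted plane
  dist <- abs(sweep(bl$rim_points, 2, bl$plane_point, "-") %*% bl$plane_normal)
  expect_lt(median(dist), 2 * max(sp))
})

test_that("identical skulls raise a no-craniectomy error", {
  m <- ph_masks_uni()
  expect_error(locate_baseline(m$pre_skull, m$pre_skull), "no craniectomy")
})

test_that("the displacement field obeys the defining identity and recovers the bulge", {
  m <- ph_masks_uni()
  meas <- measure_identity(m)
  f <- meas$field
  # dy = y_post - y_pre at every station, by definition
  expect_equal(f$samples$dy, f$samples$y_post - f$samples$y_pre,
               tolerance = 1e-12)
  # parabolic bulge of 25 mm recovered within one slice spacing
  expect_lt(abs(f$dy_max - 25), m$pre_skull$spacing[3])
  # attained near the aperture centre
  ctr <- m$ph$truth$centre
  expect_lt(sqrt(sum((f$dy_max_at[2:3] - ctr[2:3])^2)), 12)
  expect_equal(f$n_excluded, 0)
})

test_that("identical edges give an all-zero field", {
  m <- ph_masks_uni()
  bl <- locate_baseline(m$pre_skull, m$post_skull)
  edges <- extract_edge(m$pre_brain)
  f <- displacement_field(edges, edges, bl)
  expect_equal(max(abs(f$samples$dy)), 0)
  expect_equal(f$dy_max, 0)
})

test_that("herniated volume differencing is exact arithmetic with flags", {
  geom <- scan_volume(array(0, c(20, 20, 20)), c(1, 1, 1))
  a <- array(FALSE, c(20, 20, 20)); a[5:15, 5:15, 5:15] <- TRUE
  b <- a; b[16, 5:14, 5:14] <- TRUE   # 100 extra voxels of 1 mm^3
  ma <- binary_mask(a, geom); mb <- binary_mask(b, geom)
  expect_equal(as.numeric(herniated_volume(ma, ma)), 0)
  expect_equal(as.numeric(herniated_volume(ma, mb)), 0.1)
  neg <- herniated_volume(mb, ma)
  expect_true(attr(neg, "negative"))
  other <- binary_mask(a, scan_volume(array(0, c(20, 20, 20)), c(2, 1, 1)))
  expect_error(herniated_volume(ma, other), "grid")
})

test_that("phantom herniated volume matches the analytic 48 ml within 3%", {
  m <- ph_masks_uni()
  dv <- as.numeric(herniated_volume(m$pre_brain, m$post_brain))
  expect_lt(abs(dv - m$ph$truth$true_dV / 1000) / (m$ph$truth$true_dV / 1000),
            0.03)
})

test_that("displacement and volume jointly satisfy the parabolic-cap relation", {
  # measured dy_max and dV of the circular-aperture parabolic phantom
  # must be linked by dV = pi r^2 dy_max / 2 at the aperture radius
  m <- ph_masks_uni()
  meas <- measure_identity(m)
  r <- m$ph$truth$spec$aperture_height / 2
  predicted <- parabolic_cap_volume(r, meas$field$dy_max) / 1000
  expect_lt(abs(predicted - meas$dV) / meas$dV, 0.05)
})

test_that("the Flint measure overestimates the true displacement", {
  for (m in list(ph_masks_uni(), ph_masks_bif())) {
    meas <- measure_identity(m)
    expect_gte(meas$y_flint + 1e-9, meas$field$dy_max)
    expect_gte(meas$y_flint, m$ph$truth$true_dy_max - 1)
  }
})

test_that("a post-op surface on the baseline gives zero Flint displacement", {
  m <- ph_masks_uni()
  bl <- locate_baseline(m$pre_skull, m$post_skull)
  # an artificial brain edge entirely behind the baseline plane
  behind <- lapply(extract_edge(m$pre_brain), function(e) {
    e$points[, 1] <- e$points[, 1] - 40
    e
  })
  expect_equal(as.numeric(flint_displacement(behind, bl)), 0)
})

test_that("widening a bifrontal chord moves the Flint baseline but not the bulge", {
  narrow <- ph_masks_bif()
  wide <- cached("masks_bif_wide", {
    ph <- generate_phantom(phantom_spec(
      skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
      aperture_location = "bifrontal", aperture_height = 70,
      aperture_width = 92, bulge_height = 25, noise_sd = 0,
      voxel_spacing = c(2, 2, 2.5), seed = 7))
    pre_sk <- skull_mask(ph$pre); post_sk <- skull_mask(ph$post)
    list(ph = ph, pre_skull = pre_sk, post_skull = post_sk,
         pre_brain = brain_from_inner_table(pre_sk),
         post_brain = segment_brain(ph$post))
  })
  m1 <- measure_identity(narrow)
  m2 <- measure_identity(wide)
  # same planted bulge ...
  expect_lt(abs(m1$field$dy_max - m2$field$dy_max), 2.5)
  # ... but the Flint value shifts with the baseline geometry
  expect_gt(abs(m1$y_flint - m2$y_flint), 2.5)
})

test_that("area estimates behave like the rectangle and the mesh they are", {
  expect_equal(area_height_width(100, 112), 11200)
  # rectangle vs inscribed ellipse: the constant 4/pi
  for (hw in list(c(100, 112), c(37, 81), c(70, 70))) {
    ratio <- area_height_width(hw[1], hw[2]) / (pi * hw[1] * hw[2] / 4)
    expect_equal(ratio, 4 / pi, tolerance = 1e-12)
  }
  m <- ph_masks_uni()
  bl <- locate_baseline(m$pre_skull, m$post_skull)
  expect_equal(area_height_width(bl), bl$height * bl$width)
})

test_that("mesh area of a near-flat circular aperture matches the analytic patch", {
  mm <- cached("mesh_flat", {
    # large spherical head: the 35 mm aperture patch is nearly flat
    ph <- generate_phantom(phantom_spec(
      skull_outer_radius = 100, axis_ratios = c(1, 1, 1),
      aperture_height = 70, aperture_width = 70, bulge_height = 10,
      noise_sd = 0, voxel_spacing = c(2.2, 2.2, 2.2), seed = 4))
    list(pre = skull_mask(ph$pre), post = skull_mask(ph$post))
  })
  am <- area_mesh(mm$pre, mm$post)
  expect_false(attr(am, "degenerate"))
  # analytic spherical patch over the cylinder r = 35 on R = 100
  R <- 100
  patch <- 2 * pi * R * (R - sqrt(R^2 - 35^2))
  expect_lt(abs(as.numeric(am) - patch) / patch, 0.05)
  # and the flat-disc value is itself within ~8% of the patch here
  expect_lt(abs(as.numeric(am) - pi * 35^2) / (pi * 35^2), 0.08)
})

test_that("mesh area is zero for identical skulls and below height x width", {
  m <- ph_masks_uni()
  same <- area_mesh(m$pre_skull, m$pre_skull)
  expect_true(attr(same, "degenerate"))
  expect_equal(as.numeric(same), 0, tolerance = 1e-9)

  # a usable positive area on both geometries ...
  for (mm in list(ph_masks_uni(), ph_masks_bif())) {
    am <- area_mesh(mm$pre_skull, mm$post_skull)
    expect_false(attr(am, "degenerate"))
    expect_gt(as.numeric(am), 0)
  }
  # ... and on the strongly curved bifrontal opening the mesh area stays
  # below the rectangular height x width estimate
  mb <- ph_masks_bif()
  bl <- locate_baseline(mb$pre_skull, mb$post_skull)
  am <- area_mesh(mb$pre_skull, mb$post_skull)
  expect_lte(as.numeric(am), area_height_width(bl))
})

test_that("herniated volume is invariant under a common rigid transform", {
  m <- ph_masks_uni()
  dv0 <- as.numeric(herniated_volume(m$pre_brain, m$post_brain))
  tr <- rigid_from_euler(c(0, 0, 7), center = m$ph$truth$centre,
                         translation = c(5, -3, 2))
  geom <- scan_volume(array(0, dim(m$pre_brain$values)), m$pre_brain$spacing)
  pre_t <- resample_mask(m$pre_brain, tr, geom)
  post_t <- resample_mask(m$post_brain, tr, geom)
  dv1 <- as.numeric(herniated_volume(pre_t, post_t))
  expect_lt(abs(dv1 - dv0) / abs(dv0), 0.01 + 0.02)
})
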