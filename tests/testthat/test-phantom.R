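test_that("phantom generation is deterministic and respects its invariants", {
  spec <- phantom_spec(skull_outer_radius = 50, voxel_spacing = c(3, 3, 4),
                       noise_sd = 10, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  # intensities separable by threshold (with noise well below contrast)
  expect_gt(spec$intensity_skull, spec$intensity_brain)
  expect_gt(spec$intensity_brain, spec$intensity_background)
  expect_equal(a$truth$true_area,
               spec$aperture_height * spec$aperture_width)
})

test_that("zero bulge gives identical pre/post brain regions and dV = 0", {
  spec <- phantom_spec(skull_outer_radius = 50, bulge_height = 0,
                       noise_sd = 0, voxel_spacing = c(2.5, 2.5, 3),
                       seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$true_dV, 0)
  pre_brain <- ph$pre$data > 0 & ph$pre$data < 300
  post_brain <- ph$post$data > 0 & ph$post$data < 300
  expect_identical(pre_brain, post_brain)
})

test_that("worked-example geometry: r = 35 mm parabolic bulge of 25 mm gives 48,000 mm^3", {
  spec <- phantom_spec(aperture_height = 70, aperture_width = 70,
                       bulge_height = 25, bulge_profile = "parabolic")
  expect_equal(spec$aperture_height / 2, 35)
  expect_equal(phantom_true_dV(spec), pi * 35^2 * 25 / 2,
               tolerance = 1e-12)
  expect_equal(phantom_true_dV(spec), 48106, tolerance = 1e-4)
})

test_that("voxel-counted brain volume difference matches the analytic bulge integral", {
  # fine isotropic rasterisation of a compact head
  spec <- phantom_spec(skull_outer_radius = 46, axis_ratios = c(1, 1.1, 0.9),
                       aperture_height = 48, aperture_width = 48,
                       bulge_height = 14, noise_sd = 0,
                       voxel_spacing = c(0.5, 0.5, 0.5), seed = 5)
  ph <- generate_phantom(spec)
  vv <- prod(spec$voxel_spacing)
  pre_brain <- ph$pre$data > 0 & ph$pre$data < 300
  post_brain <- ph$post$data > 0 & ph$post$data < 300
  dv_vox <- (sum(post_brain) - sum(pre_brain)) * vv
  expect_lt(abs(dv_vox - ph$truth$true_dV) / ph$truth$true_dV, 0.03)
})

test_that("spherical-cap profile integrates to the cap volume", {
  spec <- phantom_spec(skull_outer_radius = 46, axis_ratios = c(1, 1.1, 0.9),
                       aperture_height = 48, aperture_width = 48,
                       bulge_height = 14, bulge_profile = "spherical_cap",
                       noise_sd = 0, voxel_spacing = c(0.6, 0.6, 0.6),
                       seed = 5)
  req <- 24
  h <- 14
  Rc <- (req^2 + h^2) / (2 * h)
  expect_equal(phantom_true_dV(spec), pi * h^2 * (Rc - h / 3),
               tolerance = 1e-12)
  ph <- generate_phantom(spec)
  vv <- prod(spec$voxel_spacing)
  dv_vox <- (sum(ph$post$data > 0 & ph$post$data < 300) -
             sum(ph$pre$data > 0 & ph$pre$data < 300)) * vv
  expect_lt(abs(dv_vox - ph$truth$true_dV) / ph$truth$true_dV, 0.03)
})

test_that("noiseless skull is exactly recoverable by one threshold", {
  ph <- ph_identity_uni()
  spec <- ph$truth$spec
  thr <- (spec$intensity_brain + spec$intensity_skull) / 2
  recovered <- ph$post$data >= thr
  expect_identical(recovered, ph$post$data == spec$intensity_skull)
})

test_that("rasterised bulge height along the aperture axis matches true_dy_max", {
  ph <- ph_identity_uni()
  spec <- ph$truth$spec
  ctr <- ph$truth$centre
  # brain extent along +x through the aperture centre, pre vs post
  iy <- round(ctr[2] / spec$voxel_spacing[2]) + 1
  iz <- round(ctr[3] / spec$voxel_spacing[3]) + 1
  brain_pre <- which(ph$pre$data[, iy, iz] > 0 & ph$pre$data[, iy, iz] < 300)
  brain_post <- which(ph$post$data[, iy, iz] > 0 & ph$post$data[, iy, iz] < 300)
  ext <- (max(brain_post) - max(brain_pre)) * spec$voxel_spacing[1]
  expect_lt(abs(ext - spec$bulge_height), spec$voxel_spacing[1] + 1e-9)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(skull_thickness = 0), "skull_thickness")
  expect_error(phantom_spec(intensity_brain = 800), "intensities")
  expect_error(phantom_spec(aperture_height = 400), "aperture")
  expect_error(phantom_spec(bulge_height = -1), "bulge_height")
})

test_that("phantom cases round-trip through the on-disk manifest", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(skull_outer_radius = 45, voxel_spacing = c(4, 4, 5),
                       noise_sd = 0, gantry_tilt_deg = 4, seed = 2)
  ph <- generate_phantom(spec)
  write_phantom_case(ph, dir)
  pre <- read_volume(file.path(dir, "pre.nii.gz"))
  post <- read_volume(file.path(dir, "post.nii.gz"))
  expect_equal(pre$data, ph$pre$data)
  expect_equal(post$gantry_tilt_deg, 4)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$true_dV, ph$truth$true_dV)
})
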