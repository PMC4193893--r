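reg_phantom <- function(mis, seed = 3) {
  generate_phantom(phantom_spec(
    skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
    bulge_height = 25, noise_sd = 0, misalignment = mis,
    voxel_spacing = c(2, 2, 2.5), seed = seed))
}

map_error <- function(found, truth, centre) {
  pts <- sweep(matrix(seq(-30, 30, length.out = 12), 4, 3), 2, centre, "+")
  pts <- rbind(pts, centre + c(30, 0, 0), centre + c(0, 30, 0),
               centre + c(0, 0, 25))
  d <- transform_points(found, pts) - transform_points(truth, pts)
  max(sqrt(rowSums(d^2)))
}

test_that("skull thresholding recovers the shell and rejects bad thresholds", {
  ph <- ph_identity_uni()
  spec <- ph$truth$spec
  mid <- (spec$intensity_brain + spec$intensity_skull) / 2
  m <- skull_mask(ph$post, threshold = mid)
  expect_identical(m$values, ph$post$data == spec$intensity_skull)
  expect_error(skull_mask(ph$post, threshold = 1e5), "threshold")

  # automatic threshold lands between the soft-tissue and bone modes
  thr <- suggest_skull_threshold(ph$post)
  expect_gt(thr, spec$intensity_brain)
  expect_lt(thr, spec$intensity_skull)
})

test_that("noisy skull mask still overlaps the true shell almost perfectly", {
  spec <- phantom_spec(skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
                       bulge_height = 25, noise_sd = 25,
                       voxel_spacing = c(2, 2, 2.5), seed = 9)
  ph <- generate_phantom(spec)
  noiseless <- ph_identity_uni()   # same geometry, different seed irrelevant
  truth_shell <- noiseless$post$data == spec$intensity_skull
  m <- skull_mask(ph$post)
  dice <- 2 * sum(m$values & truth_shell) /
    (sum(m$values) + sum(truth_shell))
  expect_gte(dice, 0.99)
})

test_that("registering a mask to itself yields the identity transform", {
  ph <- ph_identity_uni()
  m <- skull_mask(ph$post)
  reg <- rigid_register(m, m)
  expect_lt(rotation_angle(reg$transform), 0.1)
  expect_lt(sqrt(sum(reg$transform$translation^2)), 0.1)
})

test_that("a planted 5 degree / 10 mm misalignment is recovered within 0.5 deg / 0.5 mm", {
  ctr <- c(75, 85, 62)
  tru <- rigid_from_euler(c(0, 0, 5), center = ctr,
                          translation = c(6, 6, 5.3))  # |t| = 10 mm
  ph <- reg_phantom(tru)
  fixed <- skull_mask(ph$post)
  moving <- skull_mask(ph$pre)
  reg <- rigid_register(fixed, moving)
  err <- compose_transforms(invert_transform(tru), reg$transform)
  expect_lt(rotation_angle(err), 0.5)
  expect_lt(map_error(reg$transform, tru, ph$truth$centre), 0.5)
  expect_lte(reg$final_metric, reg$metric_trace[1])
  expect_true(all(diff(reg$metric_trace) <= 1e-12))

  # removing the aperture region from the moving skull must not bias the
  # fit: register the post-op (holed) skull back to the intact pre-op one
  reg_ba <- rigid_register(moving, fixed)
  err_ba <- compose_transforms(tru, reg_ba$transform)
  expect_lt(rotation_angle(err_ba), 0.5)

  # symmetry: the two directions are mutually inverse
  both <- compose_transforms(reg$transform, reg_ba$transform)
  expect_lt(rotation_angle(both), 0.5)
  expect_lt(sqrt(sum(both$translation^2)), 0.75)
})

test_that("empty masks are rejected", {
  ph <- ph_identity_uni()
  m <- skull_mask(ph$post)
  empty <- binary_mask(array(FALSE, dim(m$values)), m, role = "skull")
  expect_error(rigid_register(m, empty), "non-empty")
})

test_that("signed distance matches a brute-force evaluation on a tiny mask", {
  d <- c(9, 8, 7)
  sp <- c(1, 2, 3)
  vals <- array(FALSE, d)
  vals[3:6, 3:5, 3:4] <- TRUE
  mask <- binary_mask(vals, scan_volume(array(0, d), sp))
  sd_fast <- signed_distance(mask)
  idx <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(idx, 2, sp, "*")
  inside <- which(vals)
  outside <- which(!vals)
  brute <- numeric(prod(d))
  for (i in seq_len(prod(d))) {
    other <- if (vals[i]) outside else inside
    dd <- sqrt(rowSums(sweep(mm[other, , drop = FALSE], 2, mm[i, ], "-")^2))
    brute[i] <- if (vals[i]) -min(dd) else min(dd)
  }
  expect_equal(as.numeric(sd_fast), brute, tolerance = 1e-12)
})
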