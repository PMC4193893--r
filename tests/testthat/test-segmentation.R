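test_that("window/level maps the window onto the output range with clipping", {
  v <- scan_volume(array(c(-1000, -160, 40, 240, 700, 40), c(6, 1, 1)),
                   c(1, 1, 1))
  out <- window_level(v, window = 400, level = 40)
  expect_equal(out$data[3, 1, 1], 127.5)        # voxel at level -> midpoint
  expect_equal(out$data[1, 1, 1], 0)            # below window -> clipped
  expect_equal(out$data[5, 1, 1], 255)          # above window -> clipped
  expect_equal(out$data[2, 1, 1], 0)            # exactly at lower bound
  expect_equal(out$data[4, 1, 1], 255)          # exactly at upper bound
  expect_error(window_level(v, window = 0, level = 40), "window")

  # window spanning the full range is an affine rescale
  w <- diff(range(v$data))
  lv <- mean(range(v$data))
  full <- window_level(v, window = w, level = lv)
  expect_equal(full$data, (v$data - min(v$data)) / w * 255, tolerance = 1e-12)
})

test_that("statistical region merging obeys its contracts", {
  # constant image: one region at any granularity
  img <- matrix(5, 20, 20)
  expect_equal(max(statistical_region_merging(img, 1)), 1)
  expect_equal(max(statistical_region_merging(img, 256)), 1)

  # two half-planes separated far beyond the merging bound: exactly 2
  img2 <- cbind(matrix(0, 24, 12), matrix(400, 24, 12))
  labs <- statistical_region_merging(img2, 25)
  expect_equal(max(labs), 2)
  expect_true(all(labs[, 1:12] == labs[1, 1]))
  expect_true(all(labs[, 13:24] == labs[1, 13]))

  # granularity is monotone: Q = 1 is the weakest segmentation
  set.seed(11)
  img3 <- matrix(rnorm(900, 0, 20), 30, 30) +
    outer(seq(0, 120, length.out = 30), rep(1, 30))
  n1 <- max(statistical_region_merging(img3, 1))
  n256 <- max(statistical_region_merging(img3, 256))
  expect_lte(n1, n256)
  expect_error(statistical_region_merging(img3, 0.5), "Q")
})

test_that("region thresholding keeps the brain band and flags empty slices", {
  ph <- ph_identity_uni()
  spec <- ph$truth$spec
  k <- round(dim(ph$post$data)[3] / 2)
  sl <- ph$post$data[, , k]
  labs <- statistical_region_merging(sl, 25)
  kept <- threshold_regions(labs, sl, band = c(-150, 250))
  expect_false(attr(kept, "empty"))
  expect_identical(kept == 1, sl == spec$intensity_brain)

  none <- threshold_regions(labs, sl, band = c(1e4, 2e4))
  expect_true(attr(none, "empty"))
  all_of_them <- threshold_regions(labs, sl, band = range(sl))
  expect_true(all(all_of_them))
})

test_that("contour cleanup fills holes and leaves clean convex masks alone", {
  disc <- outer(1:40, 1:40, function(i, j) (i - 20)^2 + (j - 20)^2 <= 14^2)
  holed <- disc
  holed[18:22, 18:22] <- FALSE
  out <- active_contour_cleanup(holed)
  expect_false(attr(out, "fallback"))
  # hole filled ...
  expect_true(all(out[18:22, 18:22]))
  # ... and the outer boundary unchanged within one voxel
  grown <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(disc * 1), EBImage::makeBrush(3, "box"))) > 0
  shrunk1 <- EBImage::imageData(EBImage::erode(
    EBImage::Image(disc * 1), EBImage::makeBrush(3, "box"))) > 0
  expect_true(all(out[shrunk1]))
  expect_true(all(grown[out]))

  # already-clean convex mask is returned unchanged within one voxel
  again <- active_contour_cleanup(disc)
  shrunk <- EBImage::imageData(EBImage::erode(
    EBImage::Image(disc * 1), EBImage::makeBrush(3, "box"))) > 0
  expect_true(all(again[shrunk]))
  expect_true(all(grown[again]))
})

test_that("segmented brain matches the noiseless phantom to within 1% volume", {
  m <- ph_masks_uni()
  spec <- m$ph$truth$spec
  truth_post_brain <- m$ph$post$data == spec$intensity_brain
  seg <- m$post_brain
  vol_err <- abs(sum(seg$values) - sum(truth_post_brain)) /
    sum(truth_post_brain)
  expect_lt(vol_err, 0.01)
  dice <- 2 * sum(seg$values & truth_post_brain) /
    (sum(seg$values) + sum(truth_post_brain))
  expect_gte(dice, 0.99)
})

test_that("pre-op brain from the inner table is exactly the enclosed cavity", {
  m <- ph_masks_uni()
  spec <- m$ph$truth$spec
  truth_pre_brain <- m$ph$pre$data == spec$intensity_brain
  expect_identical(m$pre_brain$values, truth_pre_brain)
})

test_that("edge extraction reproduces a disc boundary at sub-voxel accuracy", {
  d <- c(48, 48, 3)
  sp <- c(1.5, 1.5, 5)
  ctr_ij <- c(23, 23)          # 0-based index of the centre
  R <- 22                       # mm
  g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1))
  inside <- (g$i - ctr_ij[1])^2 * sp[1]^2 + (g$j - ctr_ij[2])^2 * sp[2]^2 <= R^2
  arr <- array(FALSE, d)
  arr[, , 2] <- inside
  mask <- binary_mask(arr, scan_volume(array(0, d), sp), role = "brain")
  edges <- extract_edge(mask)
  expect_length(edges, 1)
  e <- edges[[1]]
  expect_equal(e$slice, 2)
  ctr_mm <- ctr_ij * sp[1:2]
  radii <- sqrt(rowSums(sweep(e$points, 2, ctr_mm, "-")^2))
  expect_true(all(abs(radii - R) <= max(sp[1:2])))
  # closed polygon whose shoelace area matches the voxel count within 2%
  a_poly <- craniodef:::polygon_area(e$points)
  a_vox <- sum(inside) * sp[1] * sp[2]
  expect_lt(abs(a_poly - a_vox) / a_vox, 0.02)

  empty <- binary_mask(array(FALSE, d), scan_volume(array(0, d), sp),
                       role = "brain")
  expect_length(extract_edge(empty), 0)
})
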