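# Radiomics battery: preprocessing, discretization, first-order statistics,
# 3D shape features and the 107-feature contract.

test_that("intensity rescaling maps the image range linearly onto [0, 100]", {
  a <- array(200, dim = c(6, 6, 6))
  a[2:5, 2:5, 2:5] <- seq(200, 800, length.out = 64)
  a[3, 3, 3] <- 500
  v <- volume_image(a, spacing = c(0.5, 0.5, 0.5))
  m <- seg_mask(array(1L, dim = dim(a)), spacing = v$spacing)
  pp <- preprocess(v, m)
  x500 <- (500 - 200) / (max(a) - 200) * 100
  expect_equal(pp$volume$data[3, 3, 3], x500, tolerance = 1e-12)
  expect_equal(range(pp$volume$data), c(0, 100), tolerance = 1e-12)
})

test_that("constant image rescales to all zeros", {
  v <- volume_image(array(7, dim = c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  m <- seg_mask(array(1L, dim = c(4, 4, 4)), spacing = v$spacing)
  pp <- preprocess(v, m)
  expect_true(all(pp$volume$data == 0))
})

test_that("resampling 1 mm -> 0.5 mm doubles the grid and preserves ROI volume within 5%", {
  mask <- fixture_ball_mask(r_vox = 6, dim3 = 20, spacing = 1)
  v <- volume_image(array(rnorm(20^3, 50, 5), dim = c(20, 20, 20)),
                    spacing = c(1, 1, 1))
  pp <- preprocess(v, mask, target_spacing = 0.5)
  expect_equal(dim(pp$volume$data), c(40L, 40L, 40L))
  vol_before <- sum(mask$data) * 1
  vol_after <- sum(pp$mask$data) * 0.5^3
  expect_lt(abs(vol_after - vol_before) / vol_before, 0.05)
})

test_that("empty mask after preprocessing raises an ROI error", {
  v <- volume_image(array(0, dim = c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  m <- seg_mask(array(0L, dim = c(4, 4, 4)), spacing = v$spacing)
  expect_error(preprocess(v, m), class = "anf_roi_error")
})

test_that("fixed-bin-count discretization follows the documented level rule", {
  vals <- array(0, dim = c(8, 1, 1))
  vals[] <- c(0, 20, 49.9, 50, 75, 99.9, 100, 10)
  v <- volume_image(vals, spacing = c(0.5, 0.5, 0.5))
  m <- seg_mask(array(1L, dim = dim(vals)), spacing = v$spacing)
  roi <- discretize(v, m, n_bins = 4L)
  # width 25: [0,25) -> 1, [25,50) -> 2, [50,75) -> 3, [75,100] -> 4
  expect_equal(as.vector(roi$levels),
               c(1L, 1L, 2L, 3L, 4L, 4L, 4L, 1L))
  expect_equal(roi$n_levels, 4L)
  # 8 equally spaced values with 8 bins occupy levels 1..8
  v8 <- volume_image(array(1:8, dim = c(8, 1, 1)), spacing = rep(0.5, 3))
  roi8 <- discretize(v8, m, n_bins = 8L)
  expect_equal(as.vector(roi8$levels), 1:8)
  # constant ROI collapses to a single level
  vc <- volume_image(array(5, dim = c(8, 1, 1)), spacing = rep(0.5, 3))
  roic <- discretize(vc, m, n_bins = 8L)
  expect_equal(roic$n_levels, 1L)
  expect_true(all(roic$levels[m$data == 1L] == 1L))
})

test_that("first-order statistics match hand computation on tiny ROIs", {
  v <- volume_image(array(c(2, 2, 4, 4, 9, 9, 9, 9), dim = c(2, 2, 2)),
                    spacing = c(0.5, 0.5, 0.5))
  m <- seg_mask(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), dim = c(2, 2, 2)),
                spacing = v$spacing)
  fo <- first_order_features(v, m)
  expect_length(fo, 18L)
  expect_equal(fo[["mean"]], 3)
  expect_equal(fo[["range"]], 2)
  expect_equal(fo[["variance"]], 1)            # population variance
  expect_equal(fo[["minimum"]], 2)
  expect_equal(fo[["maximum"]], 4)
  expect_equal(fo[["median"]], 3)
  expect_equal(fo[["energy"]], sum(c(2, 2, 4, 4)^2))
  expect_equal(fo[["total_energy"]], 0.125 * sum(c(2, 2, 4, 4)^2))
  expect_equal(fo[["root_mean_squared"]], sqrt(mean(c(2, 2, 4, 4)^2)))
  expect_equal(fo[["mean_absolute_deviation"]], 1)
  expect_equal(fo[["skewness"]], 0)            # symmetric two-point mass
})

test_that("percentiles follow the stated quantile rule on 1..10", {
  v <- volume_image(array(as.numeric(1:10), dim = c(10, 1, 1)),
                    spacing = rep(0.5, 3))
  m <- seg_mask(array(1L, dim = c(10, 1, 1)), spacing = v$spacing)
  fo <- first_order_features(v, m)
  expect_equal(fo[["percentile10"]], unname(quantile(1:10, 0.1)))
  expect_equal(fo[["percentile90"]], unname(quantile(1:10, 0.9)))
  expect_equal(fo[["median"]], 5.5)
  expect_equal(fo[["interquartile_range"]],
               unname(quantile(1:10, 0.75) - quantile(1:10, 0.25)))
})

test_that("constant ROI yields entropy 0, uniformity 1, degenerate moments 0", {
  v <- volume_image(array(5, dim = c(3, 3, 3)), spacing = rep(0.5, 3))
  m <- seg_mask(array(1L, dim = c(3, 3, 3)), spacing = v$spacing)
  fo <- first_order_features(v, m)
  expect_equal(fo[["entropy"]], 0)
  expect_equal(fo[["uniformity"]], 1)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["kurtosis"]], 0)
})

test_that("digital ball shape features approach the analytic sphere", {
  mask <- fixture_ball_mask(r_vox = 10, dim3 = 25, spacing = 0.5)
  sh <- shape3d_features(mask)
  expect_length(sh, 14L)
  expect_gt(sh[["sphericity"]], 0.95)
  expect_lt(sh[["sphericity"]], 1.05)
  r_mm <- 10 * 0.5
  expect_lt(abs(sh[["voxel_volume"]] - 4 / 3 * pi * r_mm^3) /
              (4 / 3 * pi * r_mm^3), 0.05)
  expect_lt(abs(sh[["max_3d_diameter"]] - 2 * r_mm) / (2 * r_mm), 0.15)
  # near-isotropic: elongation and flatness close to 1
  expect_gt(sh[["elongation"]], 0.9)
  expect_gt(sh[["flatness"]], 0.9)
})

test_that("a thin rod has small flatness and dominant major axis", {
  a <- array(0L, dim = c(14, 5, 5))
  a[3:12, 3, 3] <- 1L
  mask <- seg_mask(a, spacing = c(1, 1, 1))
  sh <- shape3d_features(mask)
  expect_gt(sh[["major_axis_length"]], 3 * sh[["minor_axis_length"]])
  expect_lt(sh[["flatness"]], 0.5)
  expect_equal(sh[["max_3d_diameter"]], 9, tolerance = 1e-9)
})

test_that("single-voxel mask raises a degenerate-shape error", {
  a <- array(0L, dim = c(4, 4, 4)); a[2, 2, 2] <- 1L
  expect_error(shape3d_features(seg_mask(a, spacing = rep(0.5, 3))),
               class = "anf_degenerate_shape_error")
})

test_that("extract_radiomics emits exactly 107 finite features with family counts", {
  set.seed(5)
  a <- array(rnorm(16^3, 40, 10), dim = c(16, 16, 16))
  msk <- array(0L, dim = c(16, 16, 16)); msk[5:12, 5:12, 5:12] <- 1L
  v <- volume_image(a, spacing = rep(0.5, 3))
  m <- seg_mask(msk, spacing = rep(0.5, 3))
  feats <- extract_radiomics(v, m)
  expect_length(feats, 107L)
  expect_true(all(is.finite(feats)))
  fam <- attr(feats, "families")
  counts <- table(fam)[c("first_order", "shape3d", "glcm", "glrlm", "glszm",
                         "ngtdm", "gldm")]
  expect_equal(unname(as.integer(counts)), c(18L, 14L, 24L, 16L, 16L, 5L, 14L))
  # determinism
  expect_identical(extract_radiomics(v, m), feats)
})

test_that("axis permutation of volume and mask leaves the feature battery unchanged", {
  set.seed(6)
  a <- array(rnorm(12^3, 40, 10), dim = c(12, 12, 12))
  msk <- array(0L, dim = c(12, 12, 12)); msk[4:9, 3:10, 5:9] <- 1L
  v <- volume_image(a, spacing = rep(0.5, 3))
  m <- seg_mask(msk, spacing = rep(0.5, 3))
  f1 <- extract_radiomics(v, m)
  vp <- volume_image(aperm(a, c(2, 3, 1)), spacing = rep(0.5, 3))
  mp <- seg_mask(aperm(msk, c(2, 3, 1)), spacing = rep(0.5, 3))
  f2 <- extract_radiomics(vp, mp)
  # first-order is permutation invariant exactly; textures up to the
  # symmetric 13-direction set, which is closed under axis permutation;
  # the three per-plane 2D diameters permute among themselves
  planar <- grep("max_2d_diameter", names(f1))
  expect_equal(f2[-planar], f1[-planar], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sort(unname(f2[planar])), sort(unname(f1[planar])),
               tolerance = 1e-9)
})
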