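make_roi <- function(vals, spacing = c(1, 1, 1)) {
  arr <- array(vals, c(length(vals), 1, 1))
  extract_roi(image_volume(arr, spacing = spacing),
              mask_volume(array(TRUE, dim(arr)), spacing = spacing))
}

test_that("re-segmentation keeps the closed interval and the morph mask", {
  roi <- make_roi(c(-50, 10, 90, 300))
  kept <- function(r) sort(as.vector(na.omit(as.vector(r$intensity))))
  expect_equal(kept(resegment_range(roi, 0, 200)), c(10, 90))
  # morphological mask untouched
  expect_identical(resegment_range(roi, 0, 200)$morph, roi$morph)
  # unbounded range is the identity
  expect_identical(resegment_range(roi)$intensity, roi$intensity)
  # closed interval: bounds are kept
  expect_equal(kept(resegment_range(roi, 10, 90)), c(10, 90))
  expect_error(resegment_range(roi, 400, 500), "empty VOI")
  expect_error(resegment_range(roi, 5, 1), "exceed")
})

test_that("outlier exclusion uses one-pass population statistics", {
  # constant ROI: sigma 0, unchanged
  roi <- make_roi(rep(7, 10))
  expect_identical(exclude_outliers(roi)$intensity, roi$intensity)
  # {0 x99, 1000}: mu = 10, sigma ~ 99.5 -> 1000 is beyond 3 sigma
  roi2 <- make_roi(c(rep(0, 99), 1000))
  kept2 <- as.vector(na.omit(as.vector(exclude_outliers(roi2, 3)$intensity)))
  expect_equal(sort(unique(kept2)), 0)
  expect_length(kept2, 99)
  # large Gaussian sample: removed fraction matches the normal tail mass
  set.seed(42)
  x <- rnorm(1e5)
  roi3 <- extract_roi(image_volume(array(x, c(100, 100, 10))),
                      mask_volume(array(TRUE, c(100, 100, 10))))
  frac <- 1 - sum(!is.na(exclude_outliers(roi3, 3)$intensity)) / 1e5
  expect_equal(frac, 2 * pnorm(-3), tolerance = 0.25)
})

test_that("FBN discretization caps the top bin and collapses constants", {
  roi <- make_roi(c(1, 2, 3, 4))
  d <- discretize(roi, "FBN", n_bins = 2)
  expect_equal(as.vector(na.omit(as.vector(d$levels))), c(1L, 1L, 2L, 2L))
  expect_identical(d$n_levels, 2L)
  # affine invariance: x -> a x + b with a > 0 preserves levels
  for (ab in list(c(3, 0), c(0.5, -7), c(100, 42))) {
    d2 <- discretize(make_roi(ab[1] * c(1, 2, 3, 4) + ab[2]), "FBN",
                     n_bins = 2)
    expect_identical(d2$levels, d$levels)
  }
  dc <- discretize(make_roi(rep(5, 6)), "FBN", n_bins = 8)
  expect_equal(unique(as.vector(na.omit(as.vector(dc$levels)))), 1L)
  expect_identical(dc$n_levels, 1L)
  expect_error(discretize(roi, "FBN", n_bins = 0), "parameter error")
})

test_that("FBS discretization anchors at lower bound or ROI minimum", {
  roi <- make_roi(c(0.5, 1.5, 2.5))
  d <- discretize(roi, "FBS", bin_width = 1, lower_bound = 0)
  expect_equal(as.vector(na.omit(as.vector(d$levels))), c(1L, 2L, 3L))
  expect_identical(d$n_levels, 3L)
  # default anchor: ROI minimum
  d2 <- discretize(roi, "FBS", bin_width = 1)
  expect_equal(as.vector(na.omit(as.vector(d2$levels))), c(1L, 2L, 3L))
  expect_error(discretize(roi, "FBS", bin_width = 0), "parameter error")
})

test_that("re-segmentation then FBS with the bound anchor is order-stable", {
  vals <- c(-10, 3, 7, 12, 25, 48, 60)
  lo <- 0; w <- 10
  roi <- make_roi(vals)
  # discretize the re-segmented ROI
  a <- discretize(resegment_range(roi, lo, 50), "FBS", bin_width = w,
                  lower_bound = lo)
  # discretize first, then drop the same voxels
  b <- discretize(roi, "FBS", bin_width = w, lower_bound = lo)
  keep <- !is.na(a$levels)
  expect_identical(a$levels[keep], b$levels[keep])
})

test_that("identity resampling reproduces the input for every method", {
  set.seed(1)
  img <- image_volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                      spacing = c(1, 2, 3), origin = c(4, 5, 6))
  for (m in c("nearest", "trilinear", "cubic_spline"))
    for (mode in c("full_3d", "slicewise_2d")) {
      out <- interpolate_image(img, img$spacing, m, mode)
      expect_equal(out$values, img$values, label = paste(m, mode))
      expect_equal(out$origin, img$origin)
    }
})

test_that("trilinear resampling is exact on affine intensity fields", {
  n <- 5
  f <- function(x, y, z) 2 * x + 3 * y + z
  vals <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    vals[i, j, k] <- f(i - 1, j - 1, k - 1)
  img <- image_volume(vals, spacing = c(1, 1, 1))
  out <- interpolate_image(img, c(0.5, 0.5, 0.5), "trilinear")
  # interior voxels: new centers land inside the input extent
  d <- dim(out$values)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    cx <- out$origin + (c(i, j, k) - 1) * out$spacing
    expect_equal(out$values[i, j, k], f(cx[1], cx[2], cx[3]),
                 tolerance = 1e-10)
  }
})

test_that("nearest-neighbour upsampling by 2 replicates interior voxels", {
  set.seed(7)
  img <- image_volume(array(rnorm(27), c(3, 3, 3)), spacing = c(2, 2, 2))
  out <- interpolate_image(img, c(1, 1, 1), "nearest")
  # interior check: each input voxel appears as a 2x2x2 block
  d <- dim(out$values)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    cx <- out$origin + (c(i, j, k) - 1) * out$spacing
    src <- pmin(pmax(round(cx / 2) + 1, 1), 3)
    expect_equal(out$values[i, j, k], img$values[src[1], src[2], src[3]])
  }
})

test_that("mask interpolation matches thresholding the scalar interpolant", {
  m <- mask_volume(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
                         c(3, 3, 3)))
  # a 1/3 mm target keeps a new center on the original voxel center
  ts <- rep(1 / 3, 3)
  out <- interpolate_mask(m, ts, "trilinear")
  # brute force: evaluate the trilinear interpolant at every new center
  field <- interpolate_image(image_volume(m$values * 1), ts, "trilinear")
  expect_identical(out$values, field$values >= 0.5)
  expect_gt(sum(out$values), 0)
  # center-aligned x2 upsampling leaves no center above 0.5: empty VOI
  expect_error(interpolate_mask(m, c(0.5, 0.5, 0.5), "trilinear"),
               "empty VOI")
  # constant all-ones mask stays all ones
  m1 <- mask_volume(array(TRUE, c(3, 3, 3)))
  out1 <- interpolate_mask(m1, c(0.5, 0.5, 0.5), "trilinear")
  expect_true(all(out1$values))
  # identity spacing: unchanged
  expect_identical(interpolate_mask(m, c(1, 1, 1), "trilinear")$values,
                   m$values)
})

test_that("slicewise 2D mode leaves the slice axis untouched", {
  img <- image_volume(array(rnorm(4 * 4 * 5), c(4, 4, 5)),
                      spacing = c(2, 2, 3))
  out <- interpolate_image(img, c(1, 1, 99), "trilinear", "slicewise_2d")
  expect_identical(dim(out$values)[3], 5L)
  expect_equal(out$spacing[3], 3)
})
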