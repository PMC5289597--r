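# Rescaling, contrast stretch, mean and bilateral filtering.

test_that("rescale_xy scales x,y only, with exact handling of identity", {
  set.seed(3)
  v <- array(runif(4 * 100 * 100), c(4, 100, 100))
  st <- tiny_stack(v, px = 0.5, dz = 2)
  out <- rescale_xy(st)
  expect_identical(dim(out$voxels), c(4L, 50L, 50L))
  expect_equal(out$px_size_xy, 1.0)
  expect_equal(out$voxel_depth_z, 2)          # z untouched

  idty <- rescale_xy(tiny_stack(v, px = 1, dz = 2))
  expect_identical(idty$voxels, v)            # identity case

  const <- rescale_xy(tiny_stack(array(7, c(2, 30, 30)), px = 0.7, dz = 1))
  expect_true(all(abs(const$voxels - 7) < 1e-12))  # bilinear of constant
})

test_that("stretch_contrast uses the ramp quantile clip points", {
  ramp <- array(0:999, c(1, 25, 40))
  st <- stretch_contrast(tiny_stack(ramp), preprocess_params())
  cp <- oracle_clip_points(0:999, 0.004)
  expect_equal(min(st$voxels), 0)
  expect_equal(max(st$voxels), 255)
  # values at the oracle clip points map to the range ends
  expect_equal(st$voxels[ramp == cp[1]], 0)
  expect_equal(st$voxels[ramp == cp[2]], 255)
  # interior value maps affinely
  mid <- 500
  expect_equal(st$voxels[ramp == mid][1],
               (mid - cp[1]) / (cp[2] - cp[1]) * 255, tolerance = 1e-9)

  const <- stretch_contrast(tiny_stack(array(5, c(2, 4, 4))))
  expect_true(all(const$voxels == 5))         # constant stack unchanged
})

test_that("any two-valued input stretches to the full 0-255 range", {
  set.seed(4)
  for (k in 1:5) {
    v <- array(sample(c(runif(1, 0, 10), runif(1, 20, 90)), 500,
                      replace = TRUE), c(5, 10, 10))
    out <- stretch_contrast(tiny_stack(v))
    expect_equal(range(out$voxels), c(0, 255))
  }
})

test_that("mean filter kernel has exactly 37 offsets at radius 3.45", {
  off <- vesseg:::cpp_disk_offsets(3.45)
  expect_identical(nrow(off), 37L)
  # oracle: enumerate dx^2+dy^2 <= 11.9025 directly
  cnt <- sum(outer((-4:4)^2, (-4:4)^2, "+") <= 3.45^2)
  expect_identical(nrow(off), cnt)
})

test_that("mean filter: constant invariance and impulse normalization", {
  const <- mean_filter(tiny_stack(array(3.5, c(2, 20, 20))))
  expect_true(all(abs(const$voxels - 3.5) < 1e-12))

  imp <- array(0, c(1, 31, 31))
  imp[1, 16, 16] <- 1
  out <- mean_filter(tiny_stack(imp))
  nz <- which(out$voxels > 0)
  expect_identical(length(nz), 37L)
  expect_true(all(abs(out$voxels[nz] - 1 / 37) < 1e-12))
})

test_that("bilateral filter preserves strong edges and bounds output", {
  # constant unchanged
  const <- bilateral_filter(tiny_stack(array(9, c(1, 10, 10))))
  expect_true(all(abs(const$voxels - 9) < 1e-12))

  # step edge with range sigma << step: no value crosses the midpoint
  step <- array(rep(c(0, 200), each = 8 * 16), c(1, 16, 16))
  p <- preprocess_params(bilateral_spatial_sigma = 2,
                         bilateral_range_sigma = 10)
  out <- bilateral_filter(tiny_stack(step), p)
  expect_true(all(out$voxels[step == 0] < 100))
  expect_true(all(out$voxels[step == 200] > 100))
  # direct weighted-sum oracle on one interior pixel of a 1D profile
  prof <- array(c(rep(0, 8), rep(200, 8)), c(1, 1, 16))
  o2 <- bilateral_filter(tiny_stack(prof), p)
  i <- 8  # last pixel of the low side (x index, 1-based)
  w <- -5:5
  xs <- pmin(pmax(i + w, 1), 16)
  vals <- prof[1, 1, xs]
  wt <- exp(-w^2 / (2 * 2^2)) * exp(-(vals - prof[1, 1, i])^2 / (2 * 10^2))
  # the range kernel is table-quantized internally: allow a small slack
  expect_lt(abs(o2$voxels[1, 1, i] - sum(wt * vals) / sum(wt)), 0.5)

  # range sigma -> large limit converges to plain Gaussian smoothing
  set.seed(5)
  v <- array(runif(16 * 16, 0, 10), c(1, 16, 16))
  big <- bilateral_filter(tiny_stack(v),
                          preprocess_params(bilateral_spatial_sigma = 2,
                                            bilateral_range_sigma = 1e7))
  gs <- vesseg:::cpp_gauss3d(v, 0, 2, 2)
  # windows are truncated differently (2.5 vs 3 sigma): compare loosely,
  # away from the borders
  expect_lt(max(abs(big$voxels[1, 6:11, 6:11] - gs[1, 6:11, 6:11])), 0.2)
})

test_that("filters keep output within the input range and dims", {
  set.seed(6)
  v <- array(runif(3 * 24 * 24, -5, 12), c(3, 24, 24))
  st <- tiny_stack(v)
  for (f in list(mean_filter, bilateral_filter, stretch_contrast)) {
    out <- f(st)
    expect_identical(dim(out$voxels), dim(v))
  }
  mf <- mean_filter(st)
  expect_gte(min(mf$voxels), min(v))
  expect_lte(max(mf$voxels), max(v))
  bf <- bilateral_filter(st)
  expect_gte(min(bf$voxels), min(v))
  expect_lte(max(bf$voxels), max(v))
})
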