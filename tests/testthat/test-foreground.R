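# Mean thresholding, ROI interpolation/masking, bounded hole filling.

test_that("threshold_mean selects the bright class per slice", {
  # half 10s, half 200s: mean 105, the bright (lucent) half is foreground
  v <- array(rep(c(10, 200), each = 200), c(1, 20, 20))
  fg <- threshold_mean(tiny_stack(v))
  expect_identical(unname(fg$mask[1, , ]), unname(v[1, , ] == 200))

  const <- threshold_mean(tiny_stack(array(5, c(3, 8, 8))))
  expect_false(any(const$mask))   # strict inequality: constant -> empty

  # slices thresholded independently
  v2 <- array(0, c(2, 4, 4))
  v2[1, , ] <- c(rep(0, 8), rep(10, 8))
  v2[2, , ] <- 100           # constant slice stays empty
  fg2 <- threshold_mean(tiny_stack(v2))
  expect_identical(sum(fg2$mask[1, , ]), 8L)
  expect_false(any(fg2$mask[2, , ]))
})

test_that("threshold_mean is invariant under positive affine rescaling", {
  set.seed(7)
  for (k in 1:5) {
    v <- array(runif(6 * 16 * 16, 0, 100), c(6, 16, 16))
    a <- runif(1, 0.1, 5); b <- runif(1, -40, 40)
    m1 <- threshold_mean(tiny_stack(v))$mask
    m2 <- threshold_mean(tiny_stack(a * v + b))$mask
    expect_identical(m1, m2)
  }
})

test_that("interpolate_roi blends resampled polygons linearly", {
  sq <- function(half, c0 = 50) cbind(
    x = c0 + c(-half, half, half, -half), y = c0 + c(-half, -half, half, half))
  a <- polygon_roi(0L, sq(20))
  b <- polygon_roi(10L, sq(40))

  # equal endpoints -> identical polygons on every slice
  same <- interpolate_roi(polygon_roi(0L, sq(20)), polygon_roi(4L, sq(20)), 5L)
  expect_length(same, 5L)
  for (z in 1:5)
    expect_equal(same[[z]]$vertices, same[[1]]$vertices)

  # midpoint slice of 40 <-> 80 squares is the side-60 square
  ser <- interpolate_roi(a, b, 11L)
  mid <- ser[[6]]$vertices
  expect_equal(max(mid[, 1]) - min(mid[, 1]), 60, tolerance = 1e-9)
  expect_equal(max(mid[, 2]) - min(mid[, 2]), 60, tolerance = 1e-9)
  expect_equal(abs(vesseg:::polygon_area(mid)), 3600, tolerance = 1)

  # n_slices = 2: resampled originals, areas within 1%
  two <- interpolate_roi(polygon_roi(0L, sq(20)), polygon_roi(1L, sq(40)), 2L)
  expect_equal(abs(vesseg:::polygon_area(two[[1]]$vertices)), 1600,
               tolerance = 16)
  expect_equal(abs(vesseg:::polygon_area(two[[2]]$vertices)), 6400,
               tolerance = 64)

  expect_error(interpolate_roi(polygon_roi(1L, sq(20)),
                               polygon_roi(4L, sq(30)), 5L), "slice 0")
})

test_that("apply_roi_mask keeps exactly the pixel centers inside", {
  all_true <- binary_stack(array(TRUE, c(1, 64, 64)), 1, 1)
  sq <- polygon_roi(0L, cbind(c(10, 30, 30, 10), c(10, 10, 30, 30)))
  ser <- interpolate_roi(sq, sq, 1L)
  out <- apply_roi_mask(all_true, ser)
  # even-odd rule with half-open boundary handling: 20 x 20 centers
  expect_identical(sum(out$mask), 400L)
  # oracle: explicit center-in-polygon count
  cnt <- sum(vapply(0:63, function(x) sum(vapply(0:63, function(y)
    vesseg:::point_in_poly(x, y, sq$vertices), TRUE)), 0L))
  expect_identical(sum(out$mask), cnt)

  # ROI covering the whole frame leaves the mask unchanged
  whole <- polygon_roi(0L, cbind(c(-1, 64, 64, -1), c(-1, -1, 64, 64)))
  out2 <- apply_roi_mask(all_true, interpolate_roi(whole, whole, 1L))
  expect_true(all(out2$mask))

  # masking only removes foreground
  set.seed(8)
  rnd <- binary_stack(array(runif(64 * 64) > 0.5, c(1, 64, 64)), 1, 1)
  out3 <- apply_roi_mask(rnd, ser)
  expect_true(all(out3$mask <= rnd$mask))
})

test_that("fill_holes_bounded fills only size-bounded enclosed holes", {
  mk_annulus <- function(r_in, n = 64) {
    d2 <- outer((seq_len(n) - n / 2)^2, (seq_len(n) - n / 2)^2, "+")
    m <- array(FALSE, c(1, n, n))
    m[1, , ] <- d2 <= 25^2 & d2 > r_in^2
    m
  }
  p0 <- holefill_params(dilation_radius_px = 0)

  # ~100 px hole (radius 5.6): filled
  small_hole <- binary_stack(mk_annulus(5.6), 1, 1)
  out <- fill_holes_bounded(small_hole, p0)
  expect_true(all(out$mask[small_hole$mask]))
  d2c <- outer((seq_len(64) - 32)^2, (seq_len(64) - 32)^2, "+")
  inner <- array(FALSE, c(1, 64, 64))
  inner[1, , ] <- d2c <= 5.6^2
  expect_true(all(out$mask[inner]))

  # ~700 px hole (radius 15): NOT filled
  big_hole <- binary_stack(mk_annulus(15), 1, 1)
  out2 <- fill_holes_bounded(big_hole, p0)
  ctr <- out2$mask[1, 32, 32]
  expect_false(ctr)

  # solid disk: unchanged apart from dilation
  disk <- mk_annulus(-1)
  outd <- fill_holes_bounded(binary_stack(disk, 1, 1), holefill_params())
  expect_true(all(outd$mask[disk]))   # superset of the dilated input
})

test_that("hole filling matches the border-flood-fill oracle on random masks", {
  set.seed(9)
  for (k in 1:25) {
    m <- matrix(runif(64 * 64) > 0.55, 64, 64)
    arr <- array(m, c(1, 64, 64))
    got <- fill_holes_bounded(binary_stack(arr, 1, 1),
                              holefill_params(dilation_radius_px = 0,
                                              hole_max_px = 40))$mask[1, , ]
    want <- oracle_fill_holes_slice(m, 0, 40)
    expect_identical(unname(got), unname(want))
  }
})

test_that("hole filling is monotone in hole_max_px", {
  set.seed(10)
  m <- array(runif(64 * 64) > 0.6, c(1, 64, 64))
  b <- binary_stack(m, 1, 1)
  prev <- fill_holes_bounded(b, holefill_params(0, 0, 0))$mask
  for (mx in c(5, 20, 100, 1000)) {
    cur <- fill_holes_bounded(b, holefill_params(0, 0, mx))$mask
    expect_true(all(cur >= prev))
    prev <- cur
  }
})
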