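# Watershed split, large-particle removal, distance maps, 3D watershed.

disk_slice <- function(n, cx, cy, r) {
  d2 <- outer((seq_len(n) - 1 - cy)^2, (seq_len(n) - 1 - cx)^2, "+")
  d2 <= r^2
}

test_that("2D watershed leaves single disks alone and splits doublets", {
  m <- array(FALSE, c(1, 64, 64))
  m[1, , ] <- disk_slice(64, 31, 31, 15)
  out <- watershed_2d_split(binary_stack(m, 1, 1))
  expect_identical(out$mask, m)          # one basin: unchanged

  empty <- watershed_2d_split(binary_stack(array(FALSE, c(2, 8, 8)), 1, 1))
  expect_false(any(empty$mask))

  # two overlapping disks, centers 24 px apart
  m2 <- array(FALSE, c(1, 80, 80))
  m2[1, , ] <- disk_slice(80, 28, 40, 15) | disk_slice(80, 52, 40, 15)
  expect_identical(max(vesseg:::cpp_label2d(m2, 8L)), 1L)   # fused before
  out2 <- watershed_2d_split(binary_stack(m2, 1, 1))
  lab <- vesseg:::cpp_label2d(out2$mask, 8L)
  expect_identical(max(lab), 2L)
  # separation line lies near the equidistant chord x = 40
  cut <- which(m2[1, , ] & !out2$mask[1, , ], arr.ind = TRUE)
  expect_true(all(abs(cut[, 2] - 1 - 40) <= 2))
})

test_that("remove_large_components_2d erodes then removes big particles", {
  p <- segment_params()
  # 200x40 rectangle: area 8000 > 6000 -> removed entirely
  m <- array(FALSE, c(1, 60, 220))
  m[1, 11:50, 11:210] <- TRUE
  out <- remove_large_components_2d(binary_stack(m, 1, 1), p)
  expect_false(any(out$mask))

  # disk radius 20 (~1257 px): kept, eroded by radius 1
  m2 <- array(FALSE, c(1, 64, 64))
  m2[1, , ] <- disk_slice(64, 31, 31, 20)
  out2 <- remove_large_components_2d(binary_stack(m2, 1, 1), p)
  ero <- vesseg:::cpp_erode_disk2d(m2, 1)
  expect_identical(out2$mask, array(ero, dim(m2)))
  expect_gt(sum(out2$mask), 1000)

  empty <- remove_large_components_2d(
    binary_stack(array(FALSE, c(1, 8, 8)), 1, 1), p)
  expect_false(any(empty$mask))
})

test_that("3D EDT matches the brute-force oracle (anisotropic)", {
  # single foreground voxel: nearest background one xy step away
  m <- array(FALSE, c(3, 5, 5))
  m[2, 3, 3] <- TRUE
  dm <- distance_map_3d(binary_stack(m, 1, 1.6))
  expect_equal(dm$values[2, 3, 3], 1.0)
  expect_true(all(dm$values[!m] == 0))

  # all background -> all zeros
  z <- distance_map_3d(binary_stack(array(FALSE, c(4, 6, 6)), 1, 1))
  expect_true(all(z$values == 0))

  # solid ball radius 10 at isotropic depth 1: max distance in [9, 10]
  bm <- ball_mask(c(24, 24, 24), 1, c(11.5, 11.5, 11.5), 10)
  dmb <- distance_map_3d(binary_stack(bm, 1, 1))
  expect_gte(max(dmb$values), 9)
  expect_lte(max(dmb$values), 10)

  # random anisotropic volumes vs brute force
  set.seed(11)
  for (dz in c(1, 1.6)) {
    m3 <- array(runif(16 * 16 * 16) > 0.7, c(16, 16, 16))
    got <- distance_map_3d(binary_stack(m3, 1, dz))$values
    want <- oracle_edt3d(m3, dz)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("distance-map smoothing preserves support, peak and mass", {
  zz <- smooth_distance_map(distance_map(array(0, c(4, 8, 8)), 1, 1))
  expect_true(all(zz$values == 0))

  bm <- ball_mask(c(36, 36, 36), 1, c(17.5, 17.5, 17.5), 12)
  dm <- distance_map_3d(binary_stack(bm, 1, 1))
  sm <- smooth_distance_map(dm, segment_params())
  # background stays exactly zero
  expect_true(all(sm$values[!bm] == 0))
  # argmax remains at the ball center
  am <- which(sm$values == max(sm$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(am - c(18.5, 18.5, 18.5)) <= 1.5))
  # the smoothing kernel itself conserves mass away from borders (the
  # clamped op can only lose the mass diffused onto the background)
  raw_sm <- vesseg:::cpp_gauss3d(dm$values, 3.45, 3.45, 3.45)
  # (border renormalization is not exactly mass-conserving)
  expect_lt(abs(sum(raw_sm) - sum(dm$values)) / sum(dm$values), 0.05)
  expect_lte(sum(sm$values), sum(raw_sm))
  expect_gt(sum(sm$values), 0.75 * sum(dm$values))
})

test_that("seeded 3D watershed labels balls, splits doublets, drops sheets", {
  p <- segment_params()
  run_ws <- function(mask, dz = 1) {
    b <- binary_stack(mask, 1, dz)
    dm <- smooth_distance_map(distance_map_3d(b), p)
    watershed_3d_seeded(dm, b, p)
  }
  # single ball: exactly one label covering the dmap >= 2 interior
  bm <- ball_mask(c(30, 30, 30), 1, c(14.5, 14.5, 14.5), 12)
  ws <- run_ws(bm)
  expect_identical(n_labels(ws), 1L)
  expect_true(all(ws$labels[!bm] == 0L))

  # fused doublet: two labels, assigned to the nearer seed
  m2 <- ball_mask(c(40, 40, 72), 1, c(21, 19.5, 19.5), 16) |
    ball_mask(c(40, 40, 72), 1, c(51, 19.5, 19.5), 16)
  expect_identical(max(vesseg:::cpp_label3d26(m2)), 1L)
  ws2 <- run_ws(m2)
  expect_identical(n_labels(ws2), 2L)
  cen <- measure_labels(ws2)
  expect_equal(sort(cen$center_x_nm), c(21, 51), tolerance = 1.5)

  # thin one-voxel sheet: dmap < 2 everywhere -> no labels
  sheet <- array(FALSE, c(8, 20, 20))
  sheet[4, 3:17, 3:17] <- TRUE
  ws3 <- run_ws(sheet, dz = 1.6)
  expect_identical(n_labels(ws3), 0L)
})

test_that("watershed label count is monotone non-increasing in seed radius", {
  set.seed(12)
  m <- ball_mask(c(30, 40, 40), 1, c(15, 19, 14), 11) |
    ball_mask(c(30, 40, 40), 1, c(15, 19, 27), 11)
  b <- binary_stack(m, 1, 1)
  prev <- Inf
  for (sr in c(1.2, 2.3, 8, 16)) {
    p <- segment_params(seed_radius_px = sr)
    dm <- smooth_distance_map(distance_map_3d(b), p)
    k <- n_labels(watershed_3d_seeded(dm, b, p))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("every labeled voxel was foreground; labels are disjoint basins", {
  set.seed(13)
  m <- array(runif(20 * 30 * 30) > 0.6, c(20, 30, 30))
  b <- binary_stack(m, 1, 1.6)
  p <- segment_params()
  dm <- smooth_distance_map(distance_map_3d(b), p)
  ws <- watershed_3d_seeded(dm, b, p)
  expect_true(all(m[ws$labels > 0L]))
  # below-threshold voxels stay background
  expect_true(all(ws$labels[dm$values < p$dmap_threshold] == 0L))
})
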