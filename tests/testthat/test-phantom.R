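# Phantom generator: determinism, ground-truth invariants, intensity
# ordering, doublets.

small_params <- function(seed = 7L, ...) {
  phantom_params(shape_vx = c(30L, 180L, 180L), n_vesicles = 4L,
                 n_rods = 1L, n_small_blobs = 1L, n_large_blobs = 0L,
                 seed = seed, ...)
}

test_that("identical seeds give bit-identical phantoms", {
  a <- generate_phantom(small_params())
  b <- generate_phantom(small_params())
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$gt, b$gt)
  expect_identical(a$roi_first$vertices, b$roi_first$vertices)
  c <- generate_phantom(small_params(seed = 8L))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("ground truth satisfies its invariants", {
  ph <- generate_phantom(small_params())
  gt <- ph$gt
  expect_identical(nrow(gt), 4L)
  # outer = inner + 2 x shell, exactly
  expect_equal(gt$outer_diameter_nm,
               gt$inner_diameter_nm + 2 * ph$params$shell_thickness_nm,
               tolerance = 1e-12)
  # pairwise center distances >= the min separation floor
  D <- as.matrix(dist(gt[, c("center_x_nm", "center_y_nm", "center_z_nm")]))
  diag(D) <- Inf
  expect_gte(min(D), ph$params$min_separation_nm)
  # lumen separation rule: distance >= r_in_i + r_in_j + shell
  req <- outer(gt$inner_diameter_nm / 2, gt$inner_diameter_nm / 2, "+") +
    ph$params$shell_thickness_nm
  diag(req) <- 0
  expect_true(all(D >= req - 1e-9))
})

test_that("n_vesicles = 0 gives pure background with empty ground truth", {
  ph <- generate_phantom(phantom_params(shape_vx = c(10L, 60L, 60L),
                                        n_vesicles = 0L, n_rods = 0L,
                                        n_small_blobs = 0L,
                                        n_large_blobs = 0L, seed = 3L))
  expect_identical(nrow(ph$gt), 0L)
  expect_identical(dim(ph$stack$voxels), c(10L, 60L, 60L))
})

test_that("intensity classes are ordered: shell darkest, lumen most lucent", {
  p <- small_params(noise_sd = 0)
  ph <- generate_phantom(p)
  v <- ph$stack$voxels
  d <- dim(v)
  zc <- (seq_len(d[1]) - 1) * p$voxel_depth_z
  class_mean <- function(f_lo, f_hi) {
    vals <- c()
    for (i in seq_len(nrow(ph$gt))) {
      c0 <- unlist(ph$gt[i, c("center_x_nm", "center_y_nm", "center_z_nm")])
      r_lo <- f_lo * ph$gt$inner_diameter_nm[i] / 2
      r_hi <- f_hi * ph$gt$inner_diameter_nm[i] / 2
      for (x in seq_len(d[3])) for (y in seq_len(d[2])) {
        la <- (x - 1 - c0[1])^2 + (y - 1 - c0[2])^2
        if (la > r_hi^2) next
        rr <- sqrt(la + (zc - c0[3])^2)
        sel <- rr >= r_lo & rr <= r_hi
        vals <- c(vals, v[sel, y, x])
      }
    }
    mean(vals)
  }
  lumen_mean <- class_mean(0, 0.8)
  shell_frac_lo <- 1 + 1.5 / 20     # just outside the lumen surface
  shell_mean <- class_mean(1.05, 1.15)
  # cytoplasm: voxels far from every vesicle, inside the cell polygon
  ok <- array(TRUE, d)
  for (i in seq_len(nrow(ph$gt))) {
    c0 <- unlist(ph$gt[i, c("center_x_nm", "center_y_nm", "center_z_nm")])
    for (x in seq_len(d[3])) for (y in seq_len(d[2])) {
      la <- (x - 1 - c0[1])^2 + (y - 1 - c0[2])^2
      if (la > 60^2) next
      ok[sqrt(la + (zc - c0[3])^2) < 40, y, x] <- FALSE
    }
  }
  ctr <- vesseg:::cpp_polygon_mask(d[2], d[3], ph$roi_first$vertices[, 1],
                          ph$roi_first$vertices[, 2])
  inside <- array(rep(as.vector(ctr), each = d[1]), d)
  cyt_mean <- mean(v[ok & inside])
  expect_lt(shell_mean, cyt_mean)
  expect_lt(cyt_mean, lumen_mean)   # clear-core ordering
})

test_that("sampled inner diameters follow the stated law", {
  # 3-standard-error band around the mean at aggregate n = 5 x 8 = 40
  ds <- unlist(lapply(1:5, function(s) {
    generate_phantom(phantom_params(shape_vx = c(30L, 210L, 210L),
                                    n_vesicles = 8L, n_rods = 0L,
                                    n_small_blobs = 0L, n_large_blobs = 0L,
                                    seed = 30L + s))$gt$inner_diameter_nm
  }))
  expect_identical(length(ds), 40L)
  expect_lt(abs(mean(ds) - 40), 3 * 5 / sqrt(length(ds)))
  expect_true(all(abs(ds - 40) <= 15 + 1e-9))   # +-3 SD truncation
})

test_that("doublets fuse below one diameter separation and not above", {
  p <- phantom_params(seed = 40L)
  far <- generate_doublet(p, 1.5)
  near <- generate_doublet(p, 0.8)
  expect_identical(nrow(near$gt), 2L)
  expect_true(all(near$gt$fused))
  expect_false(any(far$gt$fused))

  count_components <- function(db) {
    pre <- preprocess_stack(db$stack)
    fg <- threshold_mean(pre)
    fg <- apply_roi_mask(fg, interpolate_roi(db$roi_first, db$roi_last,
                                             dim(pre$voxels)[1]))
    fg <- fill_holes_bounded(fg)
    lab <- vesseg:::cpp_label3d26(fg$mask)
    # components overlapping the two vesicle sites
    G <- as.matrix(db$gt[, c("center_x_nm", "center_y_nm", "center_z_nm")])
    hit <- integer(0)
    for (i in 1:2) {
      z <- round(G[i, 3] / db$stack$voxel_depth_z) + 1
      hit <- c(hit, lab[z, round(G[i, 2]) + 1, round(G[i, 1]) + 1])
    }
    length(unique(hit[hit > 0]))
  }
  expect_identical(count_components(near), 1L)   # fused single component
  expect_identical(count_components(far), 2L)    # disjoint shells

  # determinism
  again <- generate_doublet(p, 0.8)
  expect_identical(near$stack$voxels, again$stack$voxels)
})
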