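# Per-label morphometry, exclusion criteria, edits, neighbour distances.

mk_labels <- function(m, dz = 1) {
  label_stack(array(as.integer(m), dim(m)), 1, dz)
}

digitize_ellipsoid <- function(dim3, dz, center, semi) {
  zc <- (seq_len(dim3[1]) - 1) * dz
  yc <- seq_len(dim3[2]) - 1
  xc <- seq_len(dim3[3]) - 1
  arr <- array(FALSE, dim3)
  for (x in seq_along(xc)) for (y in seq_along(yc)) {
    q <- ((xc[x] - center[1]) / semi[1])^2 + ((yc[y] - center[2]) / semi[2])^2
    if (q > 1) next
    arr[((zc - center[3]) / semi[3])^2 <= 1 - q, y, x] <- TRUE
  }
  arr
}

test_that("a digitized ball measures like the analytic sphere", {
  bm <- ball_mask(c(26, 26, 26), 1, c(12.5, 12.5, 12.5), 10)
  rec <- measure_labels(mk_labels(bm))
  expect_identical(nrow(rec), 1L)
  # volume within 2% of (4/3) pi 10^3 = 4188.8
  expect_lt(abs(rec$volume_vx - 4188.8) / 4188.8, 0.02)
  # moment diameters within 5% of 20 nm
  for (d in c(rec$diam1_nm, rec$diam2_nm, rec$diam3_nm))
    expect_lt(abs(d - 20) / 20, 0.05)
  expect_gte(rec$feret_nm, 19)
  expect_lte(rec$feret_nm, 21.5)
  expect_gt(rec$sphericity, 0.95)
  expect_lte(rec$sphericity, 1.02)
  expect_lt(rec$elongation, 1.05)
  # centroid at the construction center
  expect_equal(unname(c(rec$center_x_nm, rec$center_y_nm, rec$center_z_nm)),
               c(12.5, 12.5, 12.5), tolerance = 0.02)
})

test_that("an axis-aligned ellipsoid recovers its ordered diameters", {
  em <- digitize_ellipsoid(c(14, 26, 36), 1, c(17.5, 12.5, 6.5),
                           c(15, 10, 5))
  rec <- measure_labels(mk_labels(em))
  expect_lt(abs(rec$diam1_nm - 30) / 30, 0.06)
  expect_lt(abs(rec$diam2_nm - 20) / 20, 0.06)
  expect_lt(abs(rec$diam3_nm - 10) / 10, 0.06)
  expect_equal(rec$elongation, rec$diam1_nm / rec$diam2_nm)
  # anisotropic z sampling gives the same physical answer
  em2 <- digitize_ellipsoid(c(10, 26, 36), 1.6, c(17.5, 12.5, 6.5 * 1.6 / 2),
                            c(15, 10, 5))
  # ellipsoid with short axis along z, z sampled at 1.6 nm
  rec2 <- measure_labels(mk_labels(em2, dz = 1.6))
  expect_lt(abs(rec2$diam1_nm - 30) / 30, 0.06)
  expect_lt(abs(rec2$diam3_nm - 10) / 10, 0.12)
})

test_that("sphericity formula matches closed forms", {
  r <- 7.3
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-9)
  a <- 11
  expect_equal(sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3), tolerance = 1e-9)
  # a 10:1 cylinder has sphericity 0.579 analytically -- just *above* the
  # 0.5 cutoff (which is why the criteria also carry an elongation rule);
  # a 20:1 rod falls below it
  vol10 <- pi * 2^2 * 40; area10 <- pi * 4 * 40 + 2 * pi * 2^2
  expect_equal(sphericity(vol10, area10), 0.5793, tolerance = 1e-3)
  vol20 <- pi * 1^2 * 40; area20 <- pi * 2 * 40 + 2 * pi * 1^2
  expect_lt(sphericity(vol20, area20), 0.5)
  expect_error(sphericity(0, 10), "positive")
})

test_that("elongation is d1/d2 with the removal rule at > 2.0", {
  expect_equal(elongation(30, 10), 3)
  expect_equal(elongation(5, 5), 1)
  expect_error(elongation(3, 4))
  crit <- filter_criteria(min_volume_vx = 0)
  mk_rec <- function(elo) data.frame(label = 1L, volume_vx = 5000,
                                     sphericity = 0.9, elongation = elo)
  lab <- mk_labels(array(c(1L, rep(0L, 7)), c(2, 2, 2)))
  expect_identical(nrow(apply_criteria(mk_rec(2.01), lab, crit)$records), 0L)
  expect_identical(nrow(apply_criteria(mk_rec(1.99), lab, crit)$records), 1L)
})

test_that("apply_criteria removes failing records, compacts, idempotent", {
  lab <- array(0L, c(4, 30, 30))
  lab[1:2, 1:10, 1:10] <- 1L    # small block
  lab[1:4, 12:26, 1:15] <- 2L   # bigger block
  lab[1:2, 20:28, 20:28] <- 3L
  ls <- mk_labels(lab)
  rec <- measure_labels(ls)
  rec$sphericity <- c(0.93, 0.45, 0.93)  # force one sphericity failure
  rec$elongation <- c(1.05, 1.0, 3.0)    # and one elongation failure
  rec$volume_vx <- c(5000, 5000, 5000)
  crit <- filter_criteria(min_volume_vx = 3000)
  out <- apply_criteria(rec, ls, crit)
  expect_identical(out$records$label, 1L)
  expect_identical(sort(unique(as.integer(out$labels$labels))), c(0L, 1L))
  # voxels of removed labels are gone; label 1 voxels kept
  expect_identical(sum(out$labels$labels == 1L), sum(lab == 1L))
  # idempotent
  again <- apply_criteria(out$records, out$labels, crit)
  expect_identical(again$records, out$records)
  expect_identical(again$labels$labels, out$labels$labels)
  # volume rule: below min_volume removed (labels 1 and 3 have 200 and
  # 162 voxels; label 2 forced under the cutoff)
  rec2 <- measure_labels(ls)
  rec2$volume_vx[2] <- 100
  out2 <- apply_criteria(rec2, ls, filter_criteria(min_volume_vx = 150,
                                                   min_sphericity = 0,
                                                   max_elongation = 99))
  expect_identical(nrow(out2$records), 2L)
  expect_true(all(out2$records$volume_vx >= 150))
})

test_that("presets carry the published exclusion parameter sets", {
  ce <- preset_criteria("celegans")
  expect_equal(ce$min_volume_vx, 3000)
  expect_equal(preset_criteria("zebrafish_30k")$min_volume_vx, 6500)
  expect_equal(preset_criteria("zebrafish_20k")$min_volume_vx, 5000)
  expect_equal(ce$min_sphericity, 0.5)
  expect_equal(ce$max_elongation, 2.0)
})

test_that("delete and merge edit the label stack consistently", {
  lab <- array(0L, c(6, 40, 20))
  lab[2:5, 2:12, 2:12] <- 1L
  lab[2:5, 14:24, 2:12] <- 2L   # adjacent to 1? no: rows 12 vs 14 gap
  lab[2:5, 13, 2:12] <- 2L      # now 26-adjacent to label 1
  lab[1:3, 30:38, 10:18] <- 3L
  ls <- mk_labels(lab)
  rec <- measure_labels(ls)

  d <- delete_labels(ls, rec, 2L)
  expect_identical(nrow(d$records), 2L)
  expect_identical(max(d$labels$labels), 2L)  # compacted
  expect_error(delete_labels(ls, rec, 99L), "unknown")

  m <- merge_labels(ls, rec, 1L, 2L)
  expect_identical(nrow(m$records), 2L)
  merged_vol <- m$records$volume_vx[1]
  expect_equal(merged_vol, sum(lab %in% c(1L, 2L)))  # voxel conservation
  expect_error(merge_labels(ls, rec, 1L, 3L), "not adjacent")

  # edit list application
  e <- apply_edits(ls, rec, c("# comment", "merge 1 2", "delete 2"))
  expect_identical(nrow(e$records), 1L)
})

test_that("nearest-neighbour distances match the brute-force oracle", {
  mk_rec <- function(xyz) data.frame(label = seq_len(nrow(xyz)),
                                     center_x_nm = xyz[, 1],
                                     center_y_nm = xyz[, 2],
                                     center_z_nm = xyz[, 3])
  # line example: 0, 10, 25, 45
  line <- mk_rec(cbind(c(0, 10, 25, 45), 0, 0))
  out <- nearest_neighbor_distances(line, measure_config(n_neighbors = 2))
  expect_equal(unname(unlist(out[1, c("dist_nn1_nm", "dist_nn2_nm")])),
               c(10, 25))
  # two centers 50 apart, n = 1: both get 50
  two <- nearest_neighbor_distances(mk_rec(cbind(c(0, 50), 0, 0)),
                                    measure_config(n_neighbors = 1))
  expect_equal(two$dist_nn1_nm, c(50, 50))
  # n = 0: no columns
  zero <- nearest_neighbor_distances(line, measure_config(n_neighbors = 0))
  expect_length(grep("^dist_nn", names(zero)), 0L)
  # padding with NA when too few others
  pad <- nearest_neighbor_distances(mk_rec(cbind(c(0, 9), 0, 0)),
                                    measure_config(n_neighbors = 3))
  expect_true(is.na(pad$dist_nn2_nm[1]) && is.na(pad$dist_nn3_nm[2]))

  set.seed(20)
  for (k in 1:5) {
    xyz <- matrix(runif(3 * 12, 0, 200), ncol = 3)
    rec <- nearest_neighbor_distances(mk_rec(xyz),
                                      measure_config(n_neighbors = 3))
    D <- as.matrix(dist(xyz))
    for (i in 1:12) {
      want <- unname(sort(D[i, -i])[1:3])
      got <- unname(unlist(rec[i, c("dist_nn1_nm", "dist_nn2_nm",
                                    "dist_nn3_nm")]))
      expect_equal(got, want, tolerance = 1e-9)
      # ascending order
      expect_true(!is.unsorted(got))
    }
    # symmetry of the underlying distance matrix: if A's nearest is B at
    # d1, B's own nearest distance can be at most d1
    for (i in 1:12) {
      d1 <- rec$dist_nn1_nm[i]
      j <- which(abs(D[i, ] - d1) < 1e-12 & seq_len(12) != i)[1]
      expect_lte(rec$dist_nn1_nm[j], d1 + 1e-12)
    }
  }
})

test_that("mean and corrected diameter", {
  rec <- data.frame(diam1_nm = c(40, 48), diam2_nm = c(40, 42),
                    diam3_nm = c(40, 39))
  out <- mean_and_corrected_diameter(rec, measure_config())
  expect_equal(out$mean_diam_nm, c(40, 43))
  expect_equal(out$corrected_diam_nm, c(48.9, 51.9))
  out0 <- mean_and_corrected_diameter(rec,
    measure_config(membrane_offset_nm = 0))
  expect_equal(out0$corrected_diam_nm, out0$mean_diam_nm)
})

test_that("voxel conservation over measured labels", {
  set.seed(21)
  m <- array(sample(0:3, 8 * 20 * 20, replace = TRUE, prob = c(.7, .1, .1, .1)),
             c(8, 20, 20))
  # make each label one connected block instead: keep simple blocks
  m[] <- 0L
  m[1:4, 1:8, 1:8] <- 1L
  m[5:8, 10:18, 3:9] <- 2L
  ls <- mk_labels(m, dz = 1.6)
  rec <- measure_labels(ls)
  expect_equal(sum(rec$volume_vx), sum(m > 0))
  expect_equal(rec$volume_nm3, rec$volume_vx * 1.6)
})
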