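# Matching and quality metrics.

mk_pts <- function(xyz, label = TRUE) {
  df <- data.frame(center_x_nm = xyz[, 1], center_y_nm = xyz[, 2],
                   center_z_nm = xyz[, 3])
  if (label) df$label <- seq_len(nrow(df)) else df$id <- seq_len(nrow(df))
  df
}

test_that("identical center sets match perfectly", {
  set.seed(30)
  xyz <- matrix(runif(15, 0, 100), ncol = 3)
  res <- match_detections(mk_pts(xyz, FALSE), mk_pts(xyz), 10)
  expect_identical(res$tp, 5L)
  expect_identical(res$fp, 0L)
  expect_identical(res$fn, 0L)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$error_rate_pct, 0)
})

test_that("jittered predictions still match; spurious ones count as FP", {
  set.seed(31)
  G <- matrix(runif(18, 0, 200), ncol = 3)
  P <- G + matrix(rnorm(18, 0, 3 / sqrt(3)), ncol = 3)
  res <- match_detections(mk_pts(G, FALSE), mk_pts(P), 10)
  expect_identical(res$tp, 6L)

  P2 <- rbind(P, c(500, 500, 500))
  res2 <- match_detections(mk_pts(G, FALSE), mk_pts(P2), 10)
  expect_identical(res2$fp, 1L)
  expect_equal(res2$precision, 6 / 7)
})

test_that("assignment is optimal (exhaustive-permutation oracle, n <= 6)", {
  set.seed(32)
  for (k in 1:12) {
    ng <- sample(1:5, 1)
    np <- sample(1:6, 1)
    G <- matrix(runif(3 * ng, 0, 60), ncol = 3)
    P <- matrix(runif(3 * np, 0, 60), ncol = 3)
    cutoff <- runif(1, 10, 40)
    D <- outer(seq_len(ng), seq_len(np), function(i, j)
      sqrt((G[i, 1] - P[j, 1])^2 + (G[i, 2] - P[j, 2])^2 +
           (G[i, 3] - P[j, 3])^2))
    want <- oracle_assignment(D, cutoff)
    res <- match_detections(mk_pts(G, FALSE), mk_pts(P), cutoff)
    expect_identical(res$tp, want$tp)
    if (res$tp > 0)
      expect_equal(sum(res$pairs$center_dist_nm), want$dist_sum,
                   tolerance = 1e-9)
  }
})

test_that("matching is invariant to input order and monotone in cutoff", {
  set.seed(33)
  G <- matrix(runif(24, 0, 100), ncol = 3)
  P <- matrix(runif(30, 0, 100), ncol = 3)
  res <- match_detections(mk_pts(G, FALSE), mk_pts(P), 25)
  perm_g <- sample(nrow(G)); perm_p <- sample(nrow(P))
  res2 <- match_detections(mk_pts(G, FALSE)[perm_g, ], mk_pts(P)[perm_p, ], 25)
  expect_identical(res$tp, res2$tp)
  expect_identical(res$fp, res2$fp)
  prev <- 0L
  for (cut in c(2, 10, 25, 60, 200)) {
    tp <- match_detections(mk_pts(G, FALSE), mk_pts(P), cut)$tp
    expect_gte(tp, prev)
    prev <- tp
  }
})

test_that("metrics arithmetic and undefined cases", {
  m <- metrics(389, 8, 0)
  expect_equal(m$precision, 389 / 397, tolerance = 1e-12)
  expect_equal(m$recall, 1)
  m2 <- metrics(8, 0, 2)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$error_rate_pct, 20)
  # recall = 1 - error/100 exactly
  set.seed(34)
  for (k in 1:10) {
    tp <- sample(0:50, 1); fn <- sample(0:20, 1)
    if (tp + fn == 0) next
    mm <- metrics(tp, 3, fn)
    expect_equal(mm$recall, 1 - mm$error_rate_pct / 100, tolerance = 1e-12)
  }
  m3 <- metrics(0, 0, 0)
  expect_true(is.na(m3$precision) && is.na(m3$recall))
  m4 <- metrics(3, 1, 0)
  expect_equal(m4$error_rate_pct, 0)
})
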