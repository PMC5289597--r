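# Independent oracles used across the suite.  These deliberately use
# different algorithms than the package internals.

# brute-force anisotropic EDT: for every foreground voxel, min distance to
# any background voxel (chunked to bound memory)
oracle_edt3d <- function(mask, dz) {
  d <- dim(mask)
  idx <- which(mask)
  bgi <- which(!mask)
  out <- array(0, d)
  if (!length(idx) || !length(bgi)) return(out)
  coord <- function(i) {
    i0 <- i - 1L
    cbind(z = (i0 %% d[1]) * dz,
          y = (i0 %/% d[1]) %% d[2],
          x = i0 %/% (d[1] * d[2]))
  }
  B <- coord(bgi)
  Fg <- coord(idx)
  step <- 400L
  for (s in seq(1L, length(idx), by = step)) {
    e <- min(s + step - 1L, length(idx))
    blk <- Fg[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], B[, 1], "-")^2 +
      outer(blk[, 2], B[, 2], "-")^2 +
      outer(blk[, 3], B[, 3], "-")^2
    out[idx[s:e]] <- sqrt(apply(d2, 1, min))
  }
  out
}

# border flood fill on one 2D slice: background pixels 4-connected to the
# border, computed by iterated masked dilation (no explicit BFS)
oracle_border_background <- function(slice) {
  bg <- !slice
  reach <- matrix(FALSE, nrow(slice), ncol(slice))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(bg)] <- bg[, ncol(bg)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# fill holes of a slice per definition: background components not reachable
# from the border, with component size in [lo, hi] (size via label matrix)
oracle_fill_holes_slice <- function(slice, lo, hi) {
  reach <- oracle_border_background(slice)
  holes <- !slice & !reach
  if (!any(holes)) return(slice)
  # label holes 4-connected by repeated seeded flood
  out <- slice
  remaining <- holes
  while (any(remaining)) {
    seedi <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(slice), ncol(slice))
    comp[seedi] <- TRUE
    repeat {
      grown <- comp
      grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
      grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
      grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
      grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
      grown <- grown & remaining
      if (identical(grown, comp)) break
      comp <- grown
    }
    n <- sum(comp)
    if (n >= lo && n <= hi) out[comp] <- TRUE
    remaining <- remaining & !comp
  }
  out
}

# exhaustive optimal assignment for small instances: minimize matched
# distance sum with unmatched penalty; returns max TP achievable under the
# cutoff and the minimal distance sum among max-TP assignments
oracle_assignment <- function(D, cutoff) {
  ng <- nrow(D); np <- ncol(D)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best_tp <- 0L
  best_sum <- Inf
  # choose which gt indices map to which pred indices: iterate over
  # injections via permutations of pred columns padded with NA
  cols <- c(seq_len(np), rep(NA_integer_, max(0L, ng - np)))
  for (pp in perms(cols)) {
    tp <- 0L; s <- 0
    for (i in seq_len(ng)) {
      j <- pp[i]
      if (!is.na(j) && D[i, j] <= cutoff) { tp <- tp + 1L; s <- s + D[i, j] }
    }
    if (tp > best_tp || (tp == best_tp && s < best_sum)) {
      best_tp <- tp; best_sum <- s
    }
  }
  list(tp = best_tp, dist_sum = best_sum)
}

# digitize a solid ball into a (nz, ny, nx) logical mask; center in nm,
# voxel centers at (x, y, z*dz)
ball_mask <- function(dim3, dz, center, radius) {
  zc <- (seq_len(dim3[1]) - 1) * dz
  yc <- seq_len(dim3[2]) - 1
  xc <- seq_len(dim3[3]) - 1
  arr <- array(FALSE, dim3)
  for (x in seq_along(xc)) {
    dx2 <- (xc[x] - center[1])^2
    if (dx2 > radius^2) next
    for (y in seq_along(yc)) {
      dy2 <- (yc[y] - center[2])^2
      if (dx2 + dy2 > radius^2) next
      ok <- dx2 + dy2 + (zc - center[3])^2 <= radius^2
      arr[ok, y, x] <- TRUE
    }
  }
  arr
}

# quantile clip oracle by explicit sorting (inverse ECDF)
oracle_clip_points <- function(v, fraction) {
  s <- sort(v)
  n <- length(s)
  lo <- s[max(1L, ceiling(n * fraction / 2))]
  hi <- s[max(1L, ceiling(n * (1 - fraction / 2)))]
  c(lo, hi)
}

tiny_stack <- function(voxels, px = 1, dz = 1) {
  tomogram_stack(voxels, px, dz, "test")
}
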