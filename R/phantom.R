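# Synthetic tomogram phantoms with known ground truth.
#
# The phantom emulates what a stained, high-pressure-frozen synapse looks
# like in an electron tomogram at the 1 nm/px working scale: vesicles are
# dark membrane shells (~4.5 nm) around electron-lucent ("clear-core")
# lumina, embedded in cytoplasm rendered as a bright matrix darkened by
# correlated granular material (ribosomes, proteins); a dark membrane wall
# runs along the cell boundary, and non-vesicular confounders (tubular
# rods, undersized and oversized membrane-bounded blobs) are mixed in.
# Additive Gaussian noise and anisotropic z sampling complete the picture.

#' Phantom parameters
#'
#' Intensity levels are arbitrary units before contrast stretching; the
#' invariant `shell_level < lumen_level <= cytoplasm_level` is enforced.
#' The *realized* cytoplasm is darker than `cytoplasm_level` on average
#' because of the granules -- that contrast between clear lumina and
#' granular cytoplasm is what per-slice mean thresholding exploits.
#'
#' @param shape_vx volume dimensions `(nz, ny, nx)` in voxels.
#' @param voxel_depth_z nm per slice (default 1.6).
#' @param n_vesicles vesicle count (default 40).
#' @param inner_diam_mean_nm,inner_diam_sd_nm Gaussian law of the inner
#'   (lumen) diameter, truncated at +-3 SD (defaults 40 and 5 nm).
#' @param shell_thickness_nm membrane shell thickness (default 4.45 nm, so
#'   outer - inner = 8.9 nm).
#' @param min_separation_nm hard floor on the center-to-center distance
#'   between vesicles (default 40 nm).  On top of this floor, two vesicles
#'   must keep their *lumina* separated by at least one membrane
#'   thickness (center distance >= r_in_i + r_in_j + shell), so shells may
#'   touch -- as they do in a dense vesicle pool -- but interiors never
#'   merge except in deliberately generated doublets.
#' @param lumen_level,shell_level,cytoplasm_level mean intensities of the
#'   lumen, membrane shell, and cytoplasmic ground matrix.  Synaptic
#'   vesicles are "clear-core": the lumen is the most electron-lucent
#'   compartment, so `shell_level < cytoplasm_level < lumen_level` by
#'   default -- the contrast that per-slice mean thresholding relies on.
#' @param exterior_level intensity of the extracellular space outside the
#'   cell-boundary polygon (default 130).  Lightly stained extracellular
#'   material is electron-lucent; because the hand-traced ROI excludes it
#'   from analysis while it still enters the slice mean, it is what lifts
#'   the threshold above the crowded cytosol.
#' @param noise_sd additive Gaussian noise sigma (default 8).
#' @param texture_grain_nm correlation length of the granular cytoplasm
#'   texture (default 8 nm).
#' @param granule_fraction volume fraction of dark granular material in
#'   the cytoplasm (default 0.35).
#' @param n_rods tubular confounders (dark-walled, bright-cored capsules
#'   with interior axis ratio well above the elongation cap; default 5).
#' @param n_small_blobs vesicle-like shells below the volume minimum
#'   (default 3).
#' @param n_large_blobs oversized membrane-bounded blobs (default 2).
#' @param cell_polygon_margin_px margin between the cell boundary polygon
#'   and the frame (default 20 px).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape_vx = c(60L, 300L, 300L),
                           voxel_depth_z = 1.6,
                           n_vesicles = 40L,
                           inner_diam_mean_nm = 40,
                           inner_diam_sd_nm = 5,
                           shell_thickness_nm = 4.45,
                           min_separation_nm = 40,
                           lumen_level = 150,
                           shell_level = 60,
                           cytoplasm_level = 100,
                           exterior_level = 130,
                           noise_sd = 8,
                           texture_grain_nm = 8,
                           granule_fraction = 0.3,
                           n_rods = 5L,
                           n_small_blobs = 3L,
                           n_large_blobs = 2L,
                           cell_polygon_margin_px = 8,
                           seed = 1L) {
  stopifnot(length(shape_vx) == 3L, all(shape_vx >= 1),
            voxel_depth_z > 0, n_vesicles >= 0,
            inner_diam_mean_nm > 0, inner_diam_sd_nm >= 0,
            shell_thickness_nm > 0, min_separation_nm > 0,
            shell_level < lumen_level, shell_level < cytoplasm_level,
            noise_sd >= 0, texture_grain_nm > 0,
            granule_fraction >= 0, granule_fraction <= 1,
            n_rods >= 0, n_small_blobs >= 0, n_large_blobs >= 0,
            cell_polygon_margin_px >= 0)
  structure(as.list(environment()), class = "phantom_params")
}

# run expr with a private, seeded RNG stream, restoring the caller's state
with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic tomogram phantom
#'
#' Vesicle centers are placed by dart throwing inside the cell polygon
#' (eroded by the largest outer radius) and away from the z faces; shells
#' are rendered first, then lumina, both anti-aliased by 3x3x3 sub-voxel
#' sampling, on the granular cytoplasm background; confounders and noise
#' are added as configured.
#'
#' @param params a [phantom_params()].
#' @return A list: `stack` ([tomogram_stack()]), `gt` (ground-truth data
#'   frame: id, center, inner/outer diameter, fused flag), `roi_first` /
#'   `roi_last` ([polygon_roi()] of the cell wall on the first and last
#'   slice), `confounders` (data frame of injected non-vesicle objects),
#'   `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_phantom_seed(params$seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(params) {
  p <- params
  nz <- p$shape_vx[1]; ny <- p$shape_vx[2]; nx <- p$shape_vx[3]
  dz <- p$voxel_depth_z
  zmax_nm <- (nz - 1) * dz

  # --- cell boundary polygons (slightly irregular, first and last slice)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  r0 <- min(nx, ny) / 2 - p$cell_polygon_margin_px
  ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
  mk_poly <- function() {
    rr <- r0 * runif(length(ang), 0.93, 1.0)
    cbind(x = cx + rr * cos(ang), y = cy + rr * sin(ang))
  }
  poly_first <- mk_poly()
  poly_last <- mk_poly()

  # --- sample vesicle sizes
  draw_trunc_norm <- function(n, mu, sd) {
    if (sd == 0) return(rep(mu, n))
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- rnorm(1, mu, sd)
        if (abs(v - mu) <= 3 * sd && v > 0) break
      }
      out[i] <- v
    }
    out
  }
  d_in <- draw_trunc_norm(p$n_vesicles, p$inner_diam_mean_nm,
                          p$inner_diam_sd_nm)
  r_out_ves <- d_in / 2 + p$shell_thickness_nm

  clearance <- p$shell_thickness_nm + 2
  # precomputed inside/distance fields on the pixel grid: the packing
  # relaxation queries these millions of times
  in1 <- cpp_polygon_mask(ny, nx, poly_first[, 1], poly_first[, 2])
  in2 <- cpp_polygon_mask(ny, nx, poly_last[, 1], poly_last[, 2])
  dfield <- pmin(poly_dist_field(poly_first, nx, ny),
                 poly_dist_field(poly_last, nx, ny))
  inside_cell <- function(x, y, need) {
    xi <- min(max(as.integer(round(x)), 0L), nx - 1L) + 1L
    yi <- min(max(as.integer(round(y)), 0L), ny - 1L) + 1L
    in1[yi, xi] && in2[yi, xi] && dfield[yi, xi] >= need + 0.75
  }

  # placed objects for conflict checks: list of capsules (balls have a = b)
  placed <- list()
  conflicts <- function(a, b, r, gap = 3) {
    for (o in placed) {
      if (segseg_dist(a, b, o$a, o$b) < r + o$r + gap) return(TRUE)
    }
    FALSE
  }
  place_or_die <- function(what, fn, tries = 20000L) {
    for (i in seq_len(tries)) {
      obj <- fn()
      if (!is.null(obj)) return(obj)
    }
    stop("phantom generation: could not place ", what,
         " after ", tries, " attempts (packing infeasible?)")
  }

  # --- large blobs (oversized membrane-bounded compartments, clipped in z)
  large <- list()
  for (i in seq_len(p$n_large_blobs)) {
    obj <- place_or_die("large blob", function() {
      ri <- runif(1, 45, 52)   # interior cross-section still > 6000 px^2
      ro <- ri + p$shell_thickness_nm
      x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
      z <- if (runif(1) < 0.5) 0 else zmax_nm   # clipped at a z face
      if (!point_in_poly(x, y, poly_first) ||
          !point_in_poly(x, y, poly_last)) return(NULL)
      # oversized compartments hug (and cross) the cell wall, as large
      # organelles do at a synapse; the central pool stays placeable
      dp <- min(dist_to_poly(x, y, poly_first),
                dist_to_poly(x, y, poly_last))
      if (min(nx, ny) > 200 && (dp < 5 || dp > 20)) return(NULL)
      c0 <- c(x, y, z)
      if (conflicts(c0, c0, ro)) return(NULL)
      list(a = c0, b = c0, r = ro, r_in = ri, type = "large_blob")
    })
    placed[[length(placed) + 1L]] <- obj
    large[[length(large) + 1L]] <- obj
  }

  # --- rods (tubular organelles; interior radius small enough that no
  #     watershed fragment can pass both the volume and elongation filter)
  rods <- list()
  rod_r_in <- 6.5
  rod_r_out <- rod_r_in + p$shell_thickness_nm
  # long tubules in large volumes, shorter ones where the frame is tight
  rod_axis_len <- max(28, min(70, 0.3 * min(nx, ny)))
  for (i in seq_len(p$n_rods)) {
    obj <- place_or_die("rod", function() {
      x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
      z <- runif(1, rod_r_out + 6, zmax_nm - rod_r_out - 6)
      # keep tubules near the cell periphery (as ER tends to be), leaving
      # the central region free for the vesicle pool
      dp <- min(dist_to_poly(x, y, poly_first),
                dist_to_poly(x, y, poly_last))
      if (min(nx, ny) > 200 && dp > 60) return(NULL)
      u <- rnorm(3); u[3] <- u[3] * 0.4; u <- u / sqrt(sum(u^2))
      a <- c(x, y, z) - u * rod_axis_len / 2
      b <- c(x, y, z) + u * rod_axis_len / 2
      if (a[3] < rod_r_out + 3 || b[3] < rod_r_out + 3 ||
          a[3] > zmax_nm - rod_r_out - 3 ||
          b[3] > zmax_nm - rod_r_out - 3) return(NULL)
      for (ee in list(a, b))
        if (!inside_cell(ee[1], ee[2], rod_r_out + clearance))
          return(NULL)
      if (conflicts(a, b, rod_r_out)) return(NULL)
      list(a = a, b = b, r = rod_r_out, r_in = rod_r_in, type = "rod")
    })
    placed[[length(placed) + 1L]] <- obj
    rods[[length(rods) + 1L]] <- obj
  }

  # --- vesicles.  A realistic pool is near random-close-packing density,
  # which sequential dart throwing cannot reach; so: random darts inside
  # the region, then iterative pairwise repulsion until all constraints
  # hold.  Shells may touch (center distance down to r_in_i + r_in_j +
  # shell, with the min_separation floor) as in a dense pool; lumina stay
  # separated by a shared membrane wall.  The z band allows mild clipping
  # at the volume faces, as in any real tomogram slab.
  ves <- list()
  if (p$n_vesicles > 0) {
    n <- p$n_vesicles
    ri_v <- d_in / 2
    ro_v <- r_out_ves
    zlo_v <- pmax(10, 0.5 * ri_v + 2)
    if (any(zmax_nm - zlo_v <= zlo_v))
      stop("phantom volume too thin for the requested vesicle sizes")
    # lateral clearance keeps the *lumen* one membrane thickness away
    # from the cell wall; the shell may touch the wall (docked vesicles)
    wall_need <- ri_v + p$shell_thickness_nm + 1
    fresh_darts <- function() {
      pts <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        got <- FALSE
        for (t in seq_len(20000L)) {
          x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
          if (!inside_cell(x, y, wall_need[i])) next
          pts[i, ] <- c(x, y, runif(1, zlo_v[i], zmax_nm - zlo_v[i]))
          got <- TRUE
          break
        }
        if (!got) stop("phantom generation: cell region too small for ",
                       "vesicle ", i)
      }
      pts
    }
    pts <- fresh_darts()
    req <- outer(ri_v, ri_v, "+") + p$shell_thickness_nm
    req <- pmax(req, p$min_separation_nm)
    rod_need <- function(i, o) {
      if (o$type == "rod") ri_v[i] + o$r_in + p$shell_thickness_nm
      else ri_v[i] + (o$r - p$shell_thickness_nm) + p$shell_thickness_nm
    }
    ctr2 <- c(cx, cy)
    # staged radius growth: relax to feasibility at 60% of the pairwise
    # requirement, then grow toward 100% in small steps, re-relaxing at
    # each stage; this reaches close-packing densities where single-shot
    # repulsion jams
    relax_stage <- function(pts, scale, max_iter) {
      for (iter in seq_len(max_iter)) {
        moved <- FALSE
        D <- as.matrix(stats::dist(pts))
        viol <- which(D < req * scale - 1e-9 & upper.tri(D),
                      arr.ind = TRUE)
        if (isTRUE(getOption("vesseg.pack.debug")) && iter %% 250L == 0L)
          cat(sprintf("pack: scale %.2f iter %d viol %d maxdef %.2f\n",
                      scale, iter, nrow(viol),
                      max(0, max((req * scale - D)[upper.tri(D)]))))
        if (nrow(viol)) {
          moved <- TRUE
          for (k in seq_len(nrow(viol))) {
            i <- viol[k, 1]; j <- viol[k, 2]
            dv <- pts[j, ] - pts[i, ]
            dn <- sqrt(sum(dv^2))
            if (dn < 1e-6) { dv <- rnorm(3); dn <- sqrt(sum(dv^2)) }
            push <- (req[i, j] * scale - dn) / 2 * 1.05
            u <- dv / dn
            pts[i, ] <- pts[i, ] - u * push
            pts[j, ] <- pts[j, ] + u * push
          }
          if (iter %% 150L == 0L) {
            vio_i <- unique(as.vector(viol))
            pts[vio_i, ] <- pts[vio_i, ] +
              matrix(rnorm(3 * length(vio_i), 0, 1.5), ncol = 3)
          }
          if (iter %% 400L == 0L && nrow(viol) <= 6L) {
            # teleport persistent violators to fresh dart positions:
            # frees jammed configurations squeezed against the wall
            for (i in unique(as.vector(viol))) {
              for (t in seq_len(2000L)) {
                x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
                if (inside_cell(x, y, wall_need[i])) {
                  pts[i, ] <- c(x, y,
                                runif(1, zlo_v[i], zmax_nm - zlo_v[i]))
                  break
                }
              }
            }
          }
        }
        for (i in seq_len(n)) {
          zl <- zlo_v[i]
          if (pts[i, 3] < zl) { pts[i, 3] <- zl; moved <- TRUE }
          if (pts[i, 3] > zmax_nm - zl) {
            pts[i, 3] <- zmax_nm - zl; moved <- TRUE
          }
          for (o in placed) {
            dpo <- point_seg_dist3(pts[i, ], o$a, o$b)
            need <- rod_need(i, o)
            if (dpo < need - 1e-9) {
              moved <- TRUE
              if (iter %% 300L == 299L) {
                # squeezed between a pinned confounder and the wall:
                # teleport to a fresh position clear of all confounders
                for (t in seq_len(2000L)) {
                  x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
                  if (!inside_cell(x, y, wall_need[i])) next
                  cand <- c(x, y, runif(1, zlo_v[i], zmax_nm - zlo_v[i]))
                  clear <- TRUE
                  for (o2 in placed)
                    if (point_seg_dist3(cand, o2$a, o2$b) <
                        rod_need(i, o2)) { clear <- FALSE; break }
                  if (clear) { pts[i, ] <- cand; break }
                }
                break
              }
              q <- closest_seg_point3(pts[i, ], o$a, o$b)
              dv <- pts[i, ] - q
              dn <- sqrt(sum(dv^2))
              if (dn < 1e-6) { dv <- rnorm(3); dn <- sqrt(sum(dv^2)) }
              pts[i, ] <- pts[i, ] + dv / dn * (need - dpo) * 1.05
            }
          }
          guard <- 0L
          while (!inside_cell(pts[i, 1], pts[i, 2], wall_need[i]) &&
                 guard < 200L) {
            dirc <- ctr2 - pts[i, 1:2]
            dl <- sqrt(sum(dirc^2))
            if (dl < 1e-6) break
            pts[i, 1:2] <- pts[i, 1:2] + dirc / dl * 1.5
            moved <- TRUE
            guard <- guard + 1L
          }
        }
        if (!moved) return(list(pts = pts, ok = TRUE))
      }
      list(pts = pts, ok = FALSE)
    }
    satisfied <- function(pts) {
      D <- as.matrix(stats::dist(pts))
      if (any(D < req - 1e-9 & upper.tri(D))) return(FALSE)
      for (i in seq_len(n)) {
        if (pts[i, 3] < zlo_v[i] - 1e-9 ||
            pts[i, 3] > zmax_nm - zlo_v[i] + 1e-9) return(FALSE)
        if (!inside_cell(pts[i, 1], pts[i, 2], wall_need[i]))
          return(FALSE)
        for (o in placed)
          if (point_seg_dist3(pts[i, ], o$a, o$b) <
              rod_need(i, o) - 1e-9) return(FALSE)
      }
      TRUE
    }
    converged <- FALSE
    # grow past 1.0 so the final configuration has slack; accept as soon
    # as the true (scale 1.0) constraints hold; restart from fresh darts
    # when a particular initialization jams
    for (attempt in seq_len(4L)) {
      for (s in c(seq(0.6, 1.04, by = 0.02))) {
        res <- relax_stage(pts, min(s, 1.04), if (s < 1) 400L else 2500L)
        pts <- res$pts
        if (s >= 0.98 && satisfied(pts)) { converged <- TRUE; break }
      }
      if (converged) break
      pts <- fresh_darts()
    }
    if (!converged)
      stop("phantom generation: vesicle packing did not converge ",
           "(density infeasible for this cell region)")
    ves <- lapply(seq_len(n), function(i)
      list(a = pts[i, ], b = pts[i, ], r = ro_v[i], r_in = ri_v[i],
           type = "vesicle"))
  }

  # --- small blobs (below the volume minimum)
  small <- list()
  for (i in seq_len(p$n_small_blobs)) {
    obj <- place_or_die("small blob", function() {
      ri <- runif(1, 5, 7)
      ro <- ri + p$shell_thickness_nm
      x <- runif(1, 0, nx - 1); y <- runif(1, 0, ny - 1)
      z <- runif(1, ro + 2, zmax_nm - ro - 2)
      if (!inside_cell(x, y, ro + clearance)) return(NULL)
      c0 <- c(x, y, z)
      if (conflicts(c0, c0, ro, gap = 3)) return(NULL)
      for (v in ves)  # lumen-separation rule: shells may touch
        if (sqrt(sum((c0 - v$a)^2)) <
            ri + v$r_in + p$shell_thickness_nm + 1) return(NULL)
      list(a = c0, b = c0, r = ro, r_in = ri, type = "small_blob")
    })
    placed[[length(placed) + 1L]] <- obj
    small[[length(small) + 1L]] <- obj
  }

  objects <- c(large, rods, ves, small)
  vol <- render_scene(p, poly_first, poly_last, objects)

  gt <- if (length(ves)) {
    data.frame(id = seq_along(ves),
               center_x_nm = vapply(ves, function(v) v$a[1], 0),
               center_y_nm = vapply(ves, function(v) v$a[2], 0),
               center_z_nm = vapply(ves, function(v) v$a[3], 0),
               inner_diameter_nm = vapply(ves, function(v) 2 * v$r_in, 0),
               outer_diameter_nm = vapply(ves, function(v)
                 2 * (v$r_in + p$shell_thickness_nm), 0),
               fused = FALSE)
  } else {
    data.frame(id = integer(0), center_x_nm = numeric(0),
               center_y_nm = numeric(0), center_z_nm = numeric(0),
               inner_diameter_nm = numeric(0),
               outer_diameter_nm = numeric(0), fused = logical(0))
  }
  conf <- c(large, rods, small)
  confounders <- if (length(conf)) {
    data.frame(type = vapply(conf, function(o) o$type, ""),
               ax_nm = vapply(conf, function(o) o$a[1], 0),
               ay_nm = vapply(conf, function(o) o$a[2], 0),
               az_nm = vapply(conf, function(o) o$a[3], 0),
               bx_nm = vapply(conf, function(o) o$b[1], 0),
               by_nm = vapply(conf, function(o) o$b[2], 0),
               bz_nm = vapply(conf, function(o) o$b[3], 0),
               outer_radius_nm = vapply(conf, function(o) o$r, 0))
  } else {
    data.frame(type = character(0), ax_nm = numeric(0), ay_nm = numeric(0),
               az_nm = numeric(0), bx_nm = numeric(0), by_nm = numeric(0),
               bz_nm = numeric(0), outer_radius_nm = numeric(0))
  }

  list(stack = tomogram_stack(vol, 1.0, dz, "phantom"),
       gt = gt,
       roi_first = polygon_roi(0L, poly_first),
       roi_last = polygon_roi(nz - 1L, poly_last),
       confounders = confounders,
       params = p)
}

# Render background (granular cytoplasm + cell wall), then all shells,
# then all lumina, then additive noise.  Painting every shell before any
# lumen erases the shared wall of deliberately fused vesicle pairs.
render_scene <- function(p, poly_first, poly_last, objects) {
  nz <- p$shape_vx[1]; ny <- p$shape_vx[2]; nx <- p$shape_vx[3]
  dz <- p$voxel_depth_z
  vol <- array(p$cytoplasm_level, dim = c(nz, ny, nx))

  g <- NULL
  if (p$granule_fraction > 0) {
    tex <- array(rnorm(nz * ny * nx), dim = c(nz, ny, nx))
    sg <- p$texture_grain_nm / 2
    tex <- cpp_gauss3d(tex, sg / dz, sg, sg)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    q <- stats::quantile(tex, 1 - p$granule_fraction, names = FALSE)
    g <- array(pmin(1, pmax(0, (tex - q) / 0.6 + 0.5)), dim(vol))
    vol <- vol + (p$shell_level - p$cytoplasm_level) * g
  }

  # electron-lucent extracellular space outside the cell polygon, with a
  # faint version of the same granularity; dark membrane wall along the
  # (interpolated) cell boundary
  rois <- interpolate_roi(polygon_roi(0L, poly_first),
                          polygon_roi(nz - 1L, poly_last), nz)
  inmask <- array(FALSE, dim = c(nz, ny, nx))
  for (z in seq_len(nz))
    inmask[z, , ] <- cpp_polygon_mask(ny, nx, rois[[z]]$vertices[, 1],
                                      rois[[z]]$vertices[, 2])
  ext <- array(p$exterior_level, dim(vol))
  if (!is.null(g)) ext <- ext - 15 * g
  vol[!inmask] <- ext[!inmask]
  wall <- inmask & !array(cpp_erode_disk2d(inmask, p$shell_thickness_nm),
                          dim(inmask))
  vol[wall] <- vol[wall] * 0.1 + p$shell_level * 0.9

  vol <- vol + 0  # private copy: the renderer writes in place
  for (o in objects)
    vol <- cpp_render_shape(vol, dz, if (o$type == "rod") 1L else 0L,
                            o$a, o$b, o$r, p$shell_level, 3L)
  for (o in objects)
    vol <- cpp_render_shape(vol, dz, if (o$type == "rod") 1L else 0L,
                            o$a, o$b, o$r_in, p$lumen_level, 3L)

  if (p$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, p$noise_sd), dim(vol))
  vol
}

#' Generate a fused two-vesicle (doublet) phantom
#'
#' Two equal vesicles with inner diameter `inner_diam_mean_nm` at a center
#' separation of `separation_fraction` times that diameter, in a random 3D
#' orientation, rendered shells-first so the shared wall vanishes where it
#' falls inside the partner's lumen: below a separation fraction of about
#' 1 the two lumina form a single fused foreground component that only the
#' 3D watershed can split.
#'
#' @param params a [phantom_params()]; `shape_vx` defaults to a compact
#'   doublet volume when left at the phantom default.
#' @param separation_fraction center separation as a fraction of the
#'   vesicle diameter, in `[0.5, 1.5]`.
#' @return A list like [generate_phantom()] (gt rows flagged `fused` when
#'   the shells overlap).
#' @export
generate_doublet <- function(params = phantom_params(),
                             separation_fraction = 0.8) {
  stopifnot(inherits(params, "phantom_params"),
            separation_fraction >= 0.5, separation_fraction <= 1.5)
  p <- params
  if (identical(p$shape_vx, c(60L, 300L, 300L))) {
    # compact default volume, grown with the separation so any random 3D
    # orientation fits
    extent <- separation_fraction * p$inner_diam_mean_nm +
      p$inner_diam_mean_nm + 2 * p$shell_thickness_nm
    lat <- max(112L, as.integer(ceiling((extent + 12) / 0.8)))
    p$shape_vx <- c(max(56L, as.integer(ceiling((extent + 12) /
                                                  p$voxel_depth_z))),
                    lat, lat)
  }
  with_phantom_seed(p$seed, generate_doublet_impl(p, separation_fraction))
}

generate_doublet_impl <- function(p, separation_fraction) {
  nz <- p$shape_vx[1]; ny <- p$shape_vx[2]; nx <- p$shape_vx[3]
  dz <- p$voxel_depth_z
  zmax_nm <- (nz - 1) * dz
  d <- p$inner_diam_mean_nm
  r_in <- d / 2
  r_out <- r_in + p$shell_thickness_nm
  sep <- separation_fraction * d
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  ctr <- c((nx - 1) / 2, (ny - 1) / 2, zmax_nm / 2)
  c1 <- ctr - u * sep / 2
  c2 <- ctr + u * sep / 2
  lo <- pmin(c1, c2) - r_out
  hi <- pmax(c1, c2) + r_out
  if (lo[1] < 1 || lo[2] < 1 || lo[3] < dz ||
      hi[1] > nx - 2 || hi[2] > ny - 2 || hi[3] > zmax_nm - dz)
    stop("doublet does not fit the volume; enlarge shape_vx")
  # cell rectangle covering ~64% of the frame: like the cell polygon of
  # the full phantom, the lucent exterior band lifts the slice mean above
  # the cytoplasm bulk
  m <- round(0.1 * min(nx, ny))
  poly <- cbind(x = c(m, nx - 1 - m, nx - 1 - m, m),
                y = c(m, m, ny - 1 - m, ny - 1 - m))
  objects <- list(list(a = c1, b = c1, r = r_out, r_in = r_in,
                       type = "vesicle"),
                  list(a = c2, b = c2, r = r_out, r_in = r_in,
                       type = "vesicle"))
  vol <- render_scene(p, poly, poly, objects)
  fused <- sep < 2 * r_out
  gt <- data.frame(id = 1:2,
                   center_x_nm = c(c1[1], c2[1]),
                   center_y_nm = c(c1[2], c2[2]),
                   center_z_nm = c(c1[3], c2[3]),
                   inner_diameter_nm = d, outer_diameter_nm = 2 * r_out,
                   fused = fused)
  list(stack = tomogram_stack(vol, 1.0, dz, "doublet phantom"),
       gt = gt,
       roi_first = polygon_roi(0L, poly),
       roi_last = polygon_roi(nz - 1L, poly),
       confounders = NULL,
       params = p)
}

# ---- small geometry helpers ------------------------------------------

point_in_poly <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > y) != (poly[j, 2] > y) &&
        x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

dist_to_poly <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  best <- Inf
  for (i in seq_len(n)) {
    best <- min(best, point_seg_dist(c(x, y), poly[i, ], poly[j, ]))
    j <- i
  }
  best
}

point_seg_dist <- function(pnt, a, b) {
  ab <- b - a
  l2 <- sum(ab^2)
  t <- if (l2 == 0) 0 else max(0, min(1, sum((pnt - a) * ab) / l2))
  sqrt(sum((a + t * ab - pnt)^2))
}

# vectorized min distance from every pixel center (x = col, y = row,
# 0-based) to a closed polygon's boundary
poly_dist_field <- function(poly, nx, ny) {
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  best <- matrix(Inf, ny, nx)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    ab <- b - a
    l2 <- sum(ab^2)
    t <- if (l2 == 0) 0 else ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / l2
    t[t < 0] <- 0; t[t > 1] <- 1
    d <- sqrt((a[1] + t * ab[1] - xs)^2 + (a[2] + t * ab[2] - ys)^2)
    best <- pmin(best, d)
    j <- i
  }
  best
}

point_seg_dist3 <- function(pnt, a, b) {
  sqrt(sum((closest_seg_point3(pnt, a, b) - pnt)^2))
}

closest_seg_point3 <- function(pnt, a, b) {
  ab <- b - a
  l2 <- sum(ab^2)
  t <- if (l2 == 0) 0 else max(0, min(1, sum((pnt - a) * ab) / l2))
  a + t * ab
}

# approximate min distance between two 3D segments (dense sampling; used
# only for phantom packing, where a few nm of slack is irrelevant)
segseg_dist <- function(a1, b1, a2, b2) {
  ts <- seq(0, 1, length.out = 12L)
  best <- Inf
  for (t in ts) {
    pnt <- a1 + t * (b1 - a1)
    for (s in ts) {
      q <- a2 + s * (b2 - a2)
      best <- min(best, sqrt(sum((pnt - q)^2)))
    }
  }
  best
}
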