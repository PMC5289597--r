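# Morphometry of labeled candidates: volume, surface, fitted-ellipsoid
# diameters, Feret diameter, sphericity, elongation, neighbour distances,
# exclusion criteria and the membrane diameter correction.

#' Vesicle exclusion criteria
#'
#' A candidate is removed when `volume_vx < min_volume_vx` OR
#' `sphericity < min_sphericity` OR `elongation > max_elongation`.
#' Volumes are voxel counts at the 1 nm/px working scale.
#'
#' @param min_volume_vx minimum volume in voxels.
#' @param min_sphericity minimum sphericity (default 0.5).
#' @param max_elongation maximum major/second ellipsoid diameter ratio
#'   (default 2.0).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_volume_vx = 3000,
                            min_sphericity = 0.5,
                            max_elongation = 2.0) {
  stopifnot(min_volume_vx >= 0, min_sphericity >= 0, min_sphericity <= 1,
            max_elongation >= 1)
  structure(list(min_volume_vx = min_volume_vx,
                 min_sphericity = min_sphericity,
                 max_elongation = max_elongation),
            class = "filter_criteria")
}

#' Organism presets for the exclusion criteria
#'
#' `celegans`: min volume 3000 vx; `zebrafish_30k`: 6500 vx;
#' `zebrafish_20k`: 5000 vx; all with min sphericity 0.5 and max
#' elongation 2.0.
#'
#' @param name preset name.
#' @return A [filter_criteria()].
#' @export
preset_criteria <- function(name = c("celegans", "zebrafish_30k",
                                     "zebrafish_20k")) {
  name <- match.arg(name)
  vol <- switch(name, celegans = 3000, zebrafish_30k = 6500,
                zebrafish_20k = 5000)
  filter_criteria(min_volume_vx = vol, min_sphericity = 0.5,
                  max_elongation = 2.0)
}

#' Measurement configuration
#'
#' @param n_neighbors how many nearest-neighbour distances to report
#'   (default 3).
#' @param membrane_offset_nm offset added to the mean (inner) diameter to
#'   estimate the membrane-inclusive outer diameter; default 8.9 nm, about
#'   twice the membrane thickness.
#' @return An object of class `measure_config`.
#' @export
measure_config <- function(n_neighbors = 3L, membrane_offset_nm = 8.9) {
  stopifnot(n_neighbors >= 0, membrane_offset_nm >= 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 membrane_offset_nm = membrane_offset_nm),
            class = "measure_config")
}

#' Surface area of every label by the coarea (smoothed-gradient) method
#'
#' The binary indicator of each label is smoothed with a small physically
#' isotropic Gaussian and the surface is the integral of the gradient
#' magnitude.  Unlike naive exposed-face counting this is unbiased for
#' both curved and flat (axis-aligned) surfaces -- a digitized plane and a
#' digitized sphere both come out within a few percent -- which matters
#' because the sphericity filter must separate spheres from plate- and
#' lens-shaped debris.  Faces at the volume border are counted as surface.
#'
#' @param labels a [label_stack()].
#' @param sigma_nm smoothing sigma in nm (default 1.25).
#' @return Numeric vector of areas (nm^2) indexed by label id.
#' @export
label_surface_areas <- function(labels, sigma_nm = 1.25) {
  stopifnot(inherits(labels, "label_stack"))
  lab <- labels$labels
  dz <- labels$voxel_depth_z
  K <- max(lab)
  out <- numeric(K)
  if (K == 0L) return(out)
  d <- dim(lab)
  idx <- which(lab > 0L)
  by_lab <- split(idx, lab[idx])
  pad <- as.integer(ceiling(3 * sigma_nm)) + 2L
  padz <- as.integer(ceiling(3 * sigma_nm / dz)) + 2L
  for (nm in names(by_lab)) {
    k <- as.integer(nm)
    ii <- by_lab[[nm]] - 1L
    z <- ii %% d[1]
    y <- (ii %/% d[1]) %% d[2]
    x <- ii %/% (d[1] * d[2])
    zr <- range(z); yr <- range(y); xr <- range(x)
    nzb <- diff(zr) + 1L + 2L * padz
    nyb <- diff(yr) + 1L + 2L * pad
    nxb <- diff(xr) + 1L + 2L * pad
    chi <- array(0, c(nzb, nyb, nxb))
    chi[cbind(z - zr[1] + padz + 1L, y - yr[1] + pad + 1L,
              x - xr[1] + pad + 1L)] <- 1
    sm <- cpp_gauss3d(chi, sigma_nm / dz, sigma_nm, sigma_nm)
    gx <- (sm[, , c(2:nxb, nxb)] - sm[, , c(1, 1:(nxb - 1))]) / 2
    gy <- (sm[, c(2:nyb, nyb), ] - sm[, c(1, 1:(nyb - 1)), ]) / 2
    gz <- (sm[c(2:nzb, nzb), , ] - sm[c(1, 1:(nzb - 1)), , ]) / (2 * dz)
    out[k] <- sum(sqrt(gx^2 + gy^2 + gz^2)) * dz
  }
  out
}

#' Measure every label of a label stack
#'
#' Per label: voxel count and physical volume, centroid (nm), surface area
#' (coarea estimate, see [label_surface_areas()]), ordered
#' fitted-ellipsoid diameters from the voxel-coordinate second moments
#' (`semi-axis_i = sqrt(5 * lambda_i)`, the uniform-ellipsoid relation,
#' with the intra-voxel moment included), Feret diameter (max pairwise
#' distance between boundary voxel centers), sphericity and elongation.
#'
#' @param labels a [label_stack()].
#' @return A data frame with one row per label, ascending label id.
#' @export
measure_labels <- function(labels) {
  stopifnot(inherits(labels, "label_stack"))
  dz <- labels$voxel_depth_z
  K <- max(labels$labels)
  if (K == 0L) return(empty_records())
  rs <- cpp_region_stats(labels$labels, K, dz)
  st <- rs$stats
  surfaces <- label_surface_areas(labels)
  present <- which(st[, 1] > 0)
  rows <- lapply(present, function(i) {
    n <- st[i, 1]
    ctr <- st[i, 2:4] / n
    # covariance of voxel centers + uniform intra-voxel moment
    cxx <- st[i, 5] / n - ctr[1]^2 + 1 / 12
    cyy <- st[i, 6] / n - ctr[2]^2 + 1 / 12
    czz <- st[i, 7] / n - ctr[3]^2 + dz^2 / 12
    cxy <- st[i, 8] / n - ctr[1] * ctr[2]
    cxz <- st[i, 9] / n - ctr[1] * ctr[3]
    cyz <- st[i, 10] / n - ctr[2] * ctr[3]
    C <- matrix(c(cxx, cxy, cxz, cxy, cyy, cyz, cxz, cyz, czz), 3, 3)
    ev <- sort(pmax(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values, 1e-12),
               decreasing = TRUE)
    diams <- 2 * sqrt(5 * ev)
    surface <- surfaces[i]
    vol_nm3 <- n * dz
    feret <- cpp_feret(rs$boundary[[i]])
    data.frame(label = i,
               center_x_nm = ctr[1], center_y_nm = ctr[2],
               center_z_nm = ctr[3],
               volume_vx = n, volume_nm3 = vol_nm3,
               surface_nm2 = surface,
               feret_nm = feret,
               diam1_nm = diams[1], diam2_nm = diams[2],
               diam3_nm = diams[3],
               sphericity = sphericity(vol_nm3, surface),
               elongation = elongation(diams[1], diams[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(label = integer(0), center_x_nm = numeric(0),
             center_y_nm = numeric(0), center_z_nm = numeric(0),
             volume_vx = numeric(0), volume_nm3 = numeric(0),
             surface_nm2 = numeric(0), feret_nm = numeric(0),
             diam1_nm = numeric(0), diam2_nm = numeric(0),
             diam3_nm = numeric(0), sphericity = numeric(0),
             elongation = numeric(0))
}

#' Measure a single label
#' @param labels a [label_stack()].
#' @param label label id to measure.
#' @return A one-row record data frame.
#' @export
measure_label <- function(labels, label) {
  recs <- measure_labels(labels)
  row <- recs[recs$label == label, , drop = FALSE]
  if (nrow(row) == 0L) stop("no such label: ", label)
  row
}

#' Sphericity
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`: 1 for a perfect sphere, smaller for any
#' other shape.
#'
#' @param volume_nm3 volume (nm^3).
#' @param surface_nm2 surface area (nm^2).
#' @return Dimensionless sphericity.
#' @export
sphericity <- function(volume_nm3, surface_nm2) {
  if (any(volume_nm3 <= 0) || any(surface_nm2 <= 0))
    stop("volume and surface must be positive")
  pi^(1 / 3) * (6 * volume_nm3)^(2 / 3) / surface_nm2
}

#' Elongation
#'
#' Ratio of the largest to the second-largest fitted-ellipsoid diameter
#' (equivalently radius); >= 1 by construction.
#'
#' @param d1,d2 ordered diameters, `d1 >= d2 > 0`.
#' @return Dimensionless elongation.
#' @export
elongation <- function(d1, d2) {
  if (any(d2 <= 0) || any(d1 < d2)) stop("need d1 >= d2 > 0")
  d1 / d2
}

#' Apply the vesicle exclusion criteria
#'
#' Removes every record (and its voxels) failing the criteria; remaining
#' labels are compacted to 1..K (ascending original id) in both the label
#' stack and the records.
#'
#' @param records measured records from [measure_labels()].
#' @param labels the matching [label_stack()].
#' @param criteria a [filter_criteria()].
#' @return `list(labels, records)` after filtering.
#' @export
apply_criteria <- function(records, labels, criteria = filter_criteria()) {
  stopifnot(inherits(labels, "label_stack"),
            inherits(criteria, "filter_criteria"))
  keep <- !(records$volume_vx < criteria$min_volume_vx |
            records$sphericity < criteria$min_sphericity |
            records$elongation > criteria$max_elongation)
  kept <- records[keep, , drop = FALSE]
  remap <- integer(max(1L, max(labels$labels)))
  if (nrow(kept)) remap[kept$label] <- seq_len(nrow(kept))
  lab <- labels$labels
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  kept$label <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  list(labels = label_stack(array(lab, dim(labels$labels)),
                            labels$px_size_xy, labels$voxel_depth_z),
       records = kept)
}

#' Delete labels by id
#'
#' @param labels a [label_stack()].
#' @param records matching records.
#' @param ids label ids to delete.
#' @return `list(labels, records)` with remaining labels compacted.
#' @export
delete_labels <- function(labels, records, ids) {
  stopifnot(inherits(labels, "label_stack"))
  ids <- as.integer(ids)
  missing <- setdiff(ids, records$label)
  if (length(missing))
    stop("unknown label id(s): ", paste(missing, collapse = ", "))
  keep <- !(records$label %in% ids)
  kept <- records[keep, , drop = FALSE]
  remap <- integer(max(1L, max(labels$labels)))
  if (nrow(kept)) remap[kept$label] <- seq_len(nrow(kept))
  lab <- labels$labels
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  kept$label <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  list(labels = label_stack(array(lab, dim(labels$labels)),
                            labels$px_size_xy, labels$voxel_depth_z),
       records = kept)
}

#' Merge two labels
#'
#' Relabels `id_b`'s voxels to `id_a` and re-measures the merged particle.
#' The two components must be 26-adjacent (or overlap after dilation by
#' one voxel), the situation arising when the watershed splits one vesicle
#' in two.
#'
#' @param labels a [label_stack()].
#' @param records matching records.
#' @param id_a,id_b label ids to merge (result keeps `id_a`'s slot).
#' @return `list(labels, records)` with labels compacted.
#' @export
merge_labels <- function(labels, records, id_a, id_b) {
  stopifnot(inherits(labels, "label_stack"))
  for (id in c(id_a, id_b))
    if (!id %in% records$label) stop("unknown label id: ", id)
  if (id_a == id_b) stop("cannot merge a label with itself")
  if (!labels_adjacent(labels$labels, id_a, id_b))
    stop("labels ", id_a, " and ", id_b, " are not adjacent")
  lab <- labels$labels
  lab[lab == as.integer(id_b)] <- as.integer(id_a)
  merged <- label_stack(array(lab, dim(lab)), labels$px_size_xy,
                        labels$voxel_depth_z)
  # compact: drop b's slot, re-measure everything (cheap relative to
  # segmentation, and guarantees consistency)
  remap <- integer(max(lab))
  kept_ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  remap[kept_ids] <- seq_along(kept_ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  out <- label_stack(array(lab, dim(lab)), labels$px_size_xy,
                     labels$voxel_depth_z)
  list(labels = out, records = measure_labels(out))
}

# are two labels 26-adjacent (or identical-voxel overlapping)?
labels_adjacent <- function(lab, a, b) {
  idx <- which(lab == as.integer(a) | lab == as.integer(b))
  d <- dim(lab)
  z <- (idx - 1L) %% d[1]
  y <- ((idx - 1L) %/% d[1]) %% d[2]
  x <- (idx - 1L) %/% (d[1] * d[2])
  va <- lab[idx] == as.integer(a)
  A <- cbind(z, y, x)[va, , drop = FALSE]
  B <- cbind(z, y, x)[!va, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) return(FALSE)
  # restrict to mutual bounding boxes expanded by 1 to keep this cheap
  for (k in 1:3) {
    rng <- range(B[, k])
    A <- A[A[, k] >= rng[1] - 1L & A[, k] <= rng[2] + 1L, , drop = FALSE]
    if (!nrow(A)) return(FALSE)
    rng <- range(A[, k])
    B <- B[B[, k] >= rng[1] - 1L & B[, k] <= rng[2] + 1L, , drop = FALSE]
    if (!nrow(B)) return(FALSE)
  }
  for (i in seq_len(nrow(A))) {
    if (any(abs(B[, 1] - A[i, 1]) <= 1L & abs(B[, 2] - A[i, 2]) <= 1L &
            abs(B[, 3] - A[i, 3]) <= 1L))
      return(TRUE)
  }
  FALSE
}

#' Nearest-neighbour center distances
#'
#' For each vesicle, the ascending center-to-center Euclidean distances
#' (nm) to its `n_neighbors` closest other vesicles; missing neighbours
#' (fewer than n other vesicles) are `NA`.
#'
#' @param records measured records.
#' @param config a [measure_config()].
#' @return `records` with `dist_nn<i>_nm` columns appended and the
#'   neighbour count stored in attribute `n_neighbors`.
#' @export
nearest_neighbor_distances <- function(records, config = measure_config()) {
  n <- config$n_neighbors
  old <- grep("^dist_nn\\d+_nm$", names(records))
  if (length(old)) records <- records[, -old, drop = FALSE]
  if (n > 0) {
    m <- nrow(records)
    dm <- as.matrix(stats::dist(records[, c("center_x_nm", "center_y_nm",
                                            "center_z_nm")]))
    for (k in seq_len(n))
      records[[sprintf("dist_nn%d_nm", k)]] <- rep(NA_real_, m)
    if (m >= 2) {
      for (i in seq_len(m)) {
        dd <- sort(dm[i, -i])
        take <- seq_len(min(n, length(dd)))
        for (k in take)
          records[i, sprintf("dist_nn%d_nm", k)] <- dd[k]
      }
    }
  }
  attr(records, "n_neighbors") <- n
  records
}

#' Mean and membrane-corrected diameter
#'
#' `mean_diam_nm = (d1 + d2 + d3) / 3` (the inner, lumen-based diameter);
#' `corrected_diam_nm = mean_diam_nm + membrane_offset_nm` (the estimated
#' membrane-inclusive outer diameter).
#'
#' @param records measured records.
#' @param config a [measure_config()].
#' @return `records` with both columns set.
#' @export
mean_and_corrected_diameter <- function(records,
                                        config = measure_config()) {
  records$mean_diam_nm <-
    (records$diam1_nm + records$diam2_nm + records$diam3_nm) / 3
  records$corrected_diam_nm <-
    records$mean_diam_nm + config$membrane_offset_nm
  records
}

#' Apply a plain-text edit list (manual proof-reading)
#'
#' One directive per line: `delete <id>` or `merge <id_a> <id_b>`.
#' Directives are applied in order; label ids refer to the labeling at the
#' time the directive is applied.
#'
#' @param labels a [label_stack()].
#' @param records matching records.
#' @param lines character vector of directives (blank lines and `#`
#'   comments ignored).
#' @return `list(labels, records)`.
#' @export
apply_edits <- function(labels, records, lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (l in lines) {
    parts <- strsplit(l, "\\s+")[[1]]
    if (parts[1] == "delete" && length(parts) == 2L) {
      r <- delete_labels(labels, records, as.integer(parts[2]))
    } else if (parts[1] == "merge" && length(parts) == 3L) {
      r <- merge_labels(labels, records, as.integer(parts[2]),
                        as.integer(parts[3]))
    } else stop("bad edit directive: '", l, "'")
    labels <- r$labels
    records <- r$records
  }
  list(labels = labels, records = records)
}
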