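# Watershed segmentation of the foreground into individual candidates:
# per-slice watershed split, erosion + large-particle removal, anisotropic
# 3D distance map, Gaussian smoothing, seeded 3D watershed.

#' Segmentation parameters
#'
#' @param erosion_radius_px disk radius of the 2D erosion before
#'   large-particle removal (default 1).
#' @param max_particle_area_px per-slice 2D components larger than this are
#'   deleted (default 6000 px).
#' @param dmap_gauss_sigma Gaussian sigma (px in x/y; scaled by the voxel
#'   depth in z so the physical sigma is isotropic) for distance-map
#'   smoothing (default 3.45).
#' @param dmap_threshold voxels of the smoothed distance map below this
#'   value (nm) are excluded from watershed flooding (default 2).
#' @param seed_radius_px radius (nm = px at working scale) of the
#'   local-maximum neighbourhood used for seed detection and merging
#'   (default 2.3).
#' @param fill_basins when TRUE (default) the below-threshold rind of each
#'   particle is assigned to its basin after flooding, so a label covers
#'   the full foreground particle and measured diameters are not biased
#'   down by the distance threshold; the threshold still controls seed
#'   detection and basin growth order.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(erosion_radius_px = 1L,
                           max_particle_area_px = 6000L,
                           dmap_gauss_sigma = 3.45,
                           dmap_threshold = 2,
                           seed_radius_px = 2.3,
                           fill_basins = TRUE) {
  stopifnot(erosion_radius_px > 0, max_particle_area_px > 0,
            dmap_gauss_sigma > 0, dmap_threshold >= 0, seed_radius_px > 0,
            is.logical(fill_basins))
  structure(list(erosion_radius_px = erosion_radius_px,
                 max_particle_area_px = max_particle_area_px,
                 dmap_gauss_sigma = dmap_gauss_sigma,
                 dmap_threshold = dmap_threshold,
                 seed_radius_px = seed_radius_px,
                 fill_basins = fill_basins),
            class = "segment_params")
}

#' Per-slice distance-transform watershed split
#'
#' Classic binary watershed on each slice: 2D Euclidean distance transform,
#' local maxima (plateau-grouped, on a lightly smoothed map so digitization
#' ripples do not over-seed) as markers, priority flooding; pixels where
#' two basins meet become one-pixel-wide background separation lines.
#' Slices with a single basin are returned unchanged.
#'
#' @param binary a [binary_stack()].
#' @return The split [binary_stack()].
#' @export
watershed_2d_split <- function(binary) {
  stopifnot(inherits(binary, "binary_stack"))
  m <- cpp_watershed2d(binary$mask, 1.0)
  binary_stack(array(m, dim(binary$mask)), binary$px_size_xy,
               binary$voxel_depth_z)
}

#' Erode and remove oversized 2D components
#'
#' Each slice is eroded with a disk of `erosion_radius_px`; 8-connected
#' components with area above `max_particle_area_px` are then deleted.
#' This removes the large interconnected cytoplasmic masses that survive
#' thresholding.
#'
#' @param binary a [binary_stack()].
#' @param params a [segment_params()].
#' @return The cleaned [binary_stack()].
#' @export
remove_large_components_2d <- function(binary, params = segment_params()) {
  stopifnot(inherits(binary, "binary_stack"))
  m <- cpp_erode_disk2d(binary$mask, params$erosion_radius_px)
  lab <- cpp_label2d(m, 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    kill <- which(areas > params$max_particle_area_px)
    if (length(kill)) m[lab %in% kill] <- FALSE
  }
  binary_stack(array(m, dim(binary$mask)), binary$px_size_xy,
               binary$voxel_depth_z)
}

#' Anisotropic 3D Euclidean distance map
#'
#' Distance (nm at the 1 nm/px working scale) from each foreground voxel to
#' the nearest background voxel, with physical sampling
#' `(1, 1, voxel_depth_z)` nm.  Volume borders are not treated as
#' background.
#'
#' @param binary a [binary_stack()].
#' @return A [distance_map()].
#' @export
distance_map_3d <- function(binary) {
  stopifnot(inherits(binary, "binary_stack"))
  v <- cpp_edt3d(binary$mask, binary$voxel_depth_z)
  distance_map(array(v, dim(binary$mask)), binary$px_size_xy,
               binary$voxel_depth_z)
}

#' Smooth a distance map with a physically isotropic Gaussian
#'
#' Sigma is `dmap_gauss_sigma` in x and y and `dmap_gauss_sigma /
#' voxel_depth_z` in slice units along z; background voxels are clamped
#' back to 0 afterwards so the map's support never grows.
#'
#' @param dmap a [distance_map()].
#' @param params a [segment_params()].
#' @return The smoothed [distance_map()].
#' @export
smooth_distance_map <- function(dmap, params = segment_params()) {
  stopifnot(inherits(dmap, "distance_map"))
  s <- params$dmap_gauss_sigma
  out <- cpp_gauss3d(dmap$values, s / dmap$voxel_depth_z, s, s)
  out[dmap$values == 0] <- 0
  distance_map(array(out, dim(dmap$values)), dmap$px_size_xy,
               dmap$voxel_depth_z)
}

#' Seeded 3D watershed on a distance map
#'
#' Seeds are voxels that attain the maximum of the (smoothed) distance map
#' within a physical ball of radius `seed_radius_px`; candidate maxima
#' closer than that are merged into one seed.  Flooding proceeds from the
#' seeds in order of decreasing map value through 26-neighbourhoods,
#' restricted to foreground voxels with map value >= `dmap_threshold`;
#' voxels below the threshold stay background.  Ties are broken by lower
#' seed label, then lower linear index, so the result is deterministic.
#'
#' @param dmap the smoothed [distance_map()].
#' @param binary the foreground [binary_stack()] aligned with `dmap`.
#' @param params a [segment_params()].
#' @return A [label_stack()] of vesicle candidates.
#' @export
watershed_3d_seeded <- function(dmap, binary, params = segment_params()) {
  stopifnot(inherits(dmap, "distance_map"), inherits(binary, "binary_stack"))
  if (!identical(dim(dmap$values), dim(binary$mask)))
    stop("distance map and mask dimensions differ")
  lab <- cpp_watershed3d_seeded(dmap$values, binary$mask,
                                params$dmap_threshold,
                                params$seed_radius_px,
                                dmap$voxel_depth_z,
                                isTRUE(params$fill_basins))
  label_stack(array(lab, dim(binary$mask)), binary$px_size_xy,
              binary$voxel_depth_z)
}

#' Full segmentation pipeline on a foreground mask
#'
#' Order: 2D watershed split, erosion + large-particle removal, 3D distance
#' map, Gaussian smoothing, seeded 3D watershed.
#'
#' @param binary the hole-filled foreground [binary_stack()].
#' @param params a [segment_params()].
#' @param verbose print per-stage counts.
#' @return A [label_stack()].
#' @export
segment_stack <- function(binary, params = segment_params(),
                          verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  b <- watershed_2d_split(binary)
  say("segment: after 2D watershed, ", sum(b$mask), " foreground voxels")
  b <- remove_large_components_2d(b, params)
  say("segment: after large-particle removal, ", sum(b$mask),
      " foreground voxels")
  dm <- distance_map_3d(b)
  dm <- smooth_distance_map(dm, params)
  labs <- watershed_3d_seeded(dm, b, params)
  say("segment: 3D watershed produced ", max(labs$labels), " candidates")
  labs
}
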