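# Foreground separation: per-slice mean thresholding, interpolated cell
# boundary masking, bounded hole filling.
#
# Polarity: in stained EM tomograms the membranes and the crowded granular
# cytoplasm are electron-dense (dark), while vesicle lumina are
# electron-lucent ("clear-core" vesicles).  The per-slice mean sits between
# those classes, so the *bright* pixels -- the vesicle interiors -- are the
# foreground particles the rest of the pipeline segments.  This is what
# makes the measured diameters *inner* (lumen) diameters, which the
# membrane correction later converts to outer diameters.

#' Per-slice mean-brightness threshold
#'
#' For each slice independently, foreground = pixels with intensity
#' strictly above the slice mean (electron-lucent vesicle lumina).
#' A constant slice yields an empty foreground.  The selected pixel set is
#' invariant under positive affine rescaling of a slice's intensities.
#'
#' @param stack a preprocessed [tomogram_stack()].
#' @return A [binary_stack()].
#' @export
threshold_mean <- function(stack) {
  stopifnot(inherits(stack, "tomogram_stack"))
  v <- stack$voxels
  d <- dim(v)
  means <- apply(v, 1, mean)
  mask <- v > array(rep(means, d[2] * d[3]), d)
  binary_stack(mask, stack$px_size_xy, stack$voxel_depth_z)
}

#' Interpolate the cell boundary between the first and last slice
#'
#' Both polygons are resampled to a common vertex count by arc length,
#' oriented counterclockwise, and aligned so both start at their
#' maximal-x vertex; the polygon of slice z is the vertex-wise linear blend
#' with weight `z / (n_slices - 1)`.
#'
#' @param first,last hand-traced [polygon_roi()] for slice 0 and slice
#'   `n_slices - 1`.
#' @param n_slices number of slices to cover.
#' @param n_vertices common vertex count after resampling (default 128).
#' @return A `roi_series`: list of one [polygon_roi()] per slice.
#' @export
interpolate_roi <- function(first, last, n_slices, n_vertices = 128L) {
  stopifnot(inherits(first, "polygon_roi"), inherits(last, "polygon_roi"),
            n_slices >= 1L)
  if (n_slices == 1L) {
    out <- list(polygon_roi(0L, resample_polygon(first$vertices,
                                                 n_vertices)))
    class(out) <- "roi_series"
    return(out)
  }
  if (first$slice_index != 0L || last$slice_index != n_slices - 1L)
    stop("first ROI must be on slice 0 and last on slice n_slices - 1 (",
         n_slices - 1L, "), got ", first$slice_index, " and ",
         last$slice_index)
  a <- resample_polygon(first$vertices, n_vertices)
  b <- resample_polygon(last$vertices, n_vertices)
  out <- lapply(seq_len(n_slices) - 1L, function(z) {
    w <- z / (n_slices - 1)
    polygon_roi(z, (1 - w) * a + w * b)
  })
  class(out) <- "roi_series"
  out
}

# Resample a closed polygon to n equally spaced (by arc length) vertices,
# counterclockwise, starting at the maximal-x vertex (ties: larger y).
resample_polygon <- function(v, n = 128L) {
  if (polygon_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  start <- which(v[, 1] == max(v[, 1]))
  if (length(start) > 1L) start <- start[which.max(v[start, 2])]
  idx <- c(start:nrow(v), seq_len(start - 1L))
  v <- v[idx, , drop = FALSE]
  closed <- rbind(v, v[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon")
  at <- total * (seq_len(n) - 1L) / n
  xs <- stats::approx(cum, closed[, 1], xout = at, ties = "ordered")$y
  ys <- stats::approx(cum, closed[, 2], xout = at, ties = "ordered")$y
  cbind(x = xs, y = ys)
}

#' Mask the foreground with a cell-boundary ROI series
#'
#' Pixels whose center falls outside the slice's polygon (even-odd rule)
#' are set to background.
#'
#' @param binary a [binary_stack()].
#' @param rois a `roi_series` from [interpolate_roi()].
#' @return The masked [binary_stack()].
#' @export
apply_roi_mask <- function(binary, rois) {
  stopifnot(inherits(binary, "binary_stack"))
  d <- dim(binary$mask)
  if (length(rois) != d[1])
    stop("need exactly one polygon per slice (", d[1], "), got ",
         length(rois))
  mask <- binary$mask
  for (z in seq_len(d[1])) {
    poly <- rois[[z]]$vertices
    inside <- cpp_polygon_mask(d[2], d[3], poly[, 1], poly[, 2])
    mask[z, , ] <- mask[z, , ] & inside
  }
  binary_stack(mask, binary$px_size_xy, binary$voxel_depth_z)
}

#' Hole-fill parameters
#'
#' @param dilation_radius_px radius of the pre-fill dilation disk
#'   (default 1, the smallest dilation).
#' @param hole_min_px,hole_max_px inclusive hole-area bounds in pixels
#'   (defaults 0 and 575); holes outside the range are left open so large
#'   enclosed background regions -- e.g. the membrane annulus around a
#'   normal-sized vesicle -- are not swallowed.
#' @return An object of class `holefill_params`.
#' @export
holefill_params <- function(dilation_radius_px = 1L, hole_min_px = 0L,
                            hole_max_px = 575L) {
  stopifnot(dilation_radius_px >= 0, hole_min_px >= 0,
            hole_min_px <= hole_max_px)
  structure(list(dilation_radius_px = dilation_radius_px,
                 hole_min_px = hole_min_px, hole_max_px = hole_max_px),
            class = "holefill_params")
}

#' Dilate and fill bounded holes, per slice
#'
#' Each slice is dilated with a disk of `dilation_radius_px`, then
#' background components (4-connected) that do not touch the slice border
#' and whose area lies in `[hole_min_px, hole_max_px]` are filled.  The
#' dilation is not undone.
#'
#' @param binary a [binary_stack()].
#' @param params a [holefill_params()].
#' @return The dilated, hole-filled [binary_stack()].
#' @export
fill_holes_bounded <- function(binary, params = holefill_params()) {
  stopifnot(inherits(binary, "binary_stack"))
  m <- binary$mask
  if (params$dilation_radius_px > 0)
    m <- cpp_dilate_disk2d(m, params$dilation_radius_px)
  m <- cpp_fill_holes2d(m, params$hole_min_px, params$hole_max_px)
  binary_stack(array(m, dim(binary$mask)), binary$px_size_xy,
               binary$voxel_depth_z)
}
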