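# Preprocessing: rescale to the 1 nm/px working scale, global contrast
# stretch, per-slice mean and bilateral filtering.

#' Preprocessing parameters
#'
#' @param target_px_nm nm per pixel after rescaling (default 1).
#' @param saturation_fraction fraction of pixels allowed to saturate during
#'   the contrast stretch, split evenly between the dark and bright tails
#'   (default 0.004, i.e. 0.4\%).
#' @param mean_radius_px radius of the flat circular mean-filter kernel in
#'   px (default 3.45; the kernel then contains exactly 37 offsets).
#' @param bilateral_spatial_sigma spatial sigma of the bilateral filter, px.
#' @param bilateral_range_sigma range sigma of the bilateral filter, in
#'   intensity units on the stretched 0-255 scale.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(target_px_nm = 1.0,
                              saturation_fraction = 0.004,
                              mean_radius_px = 3.45,
                              bilateral_spatial_sigma = 3,
                              bilateral_range_sigma = 50) {
  stopifnot(target_px_nm > 0,
            saturation_fraction >= 0, saturation_fraction < 0.5,
            mean_radius_px > 0,
            bilateral_spatial_sigma > 0, bilateral_range_sigma > 0)
  structure(list(target_px_nm = target_px_nm,
                 saturation_fraction = saturation_fraction,
                 mean_radius_px = mean_radius_px,
                 bilateral_spatial_sigma = bilateral_spatial_sigma,
                 bilateral_range_sigma = bilateral_range_sigma),
            class = "preprocess_params")
}

#' Rescale a stack to the working pixel size in x and y
#'
#' Bilinear interpolation in x and y only; the z dimension and voxel depth
#' are left untouched so the stack keeps its true axial sampling.
#'
#' @param stack a [tomogram_stack()].
#' @param params a [preprocess_params()].
#' @return A rescaled [tomogram_stack()] at `target_px_nm` nm/px.
#' @export
rescale_xy <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "tomogram_stack"))
  f <- stack$px_size_xy / params$target_px_nm
  d <- dim(stack$voxels)
  ony <- max(1L, as.integer(round(d[2] * f)))
  onx <- max(1L, as.integer(round(d[3] * f)))
  if (ony == d[2] && onx == d[3]) {
    out <- stack$voxels
  } else {
    out <- cpp_rescale_bilinear(stack$voxels, ony, onx)
  }
  tomogram_stack(out, params$target_px_nm, stack$voxel_depth_z,
                 stack$source_path)
}

#' Global histogram stretch with bounded saturation
#'
#' Clip points are the empirical `f/2` and `1 - f/2` quantiles of the whole
#' stack (`f` = `saturation_fraction`); intensities are mapped affinely so
#' the clip points land on 0 and 255, then clipped.  Constant stacks are
#' returned unchanged.
#'
#' @inheritParams rescale_xy
#' @return A [tomogram_stack()] on the 0-255 scale.
#' @export
stretch_contrast <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "tomogram_stack"))
  v <- stack$voxels
  f <- params$saturation_fraction
  q <- stats::quantile(v, c(f / 2, 1 - f / 2), names = FALSE, type = 1)
  if (q[2] <= q[1]) return(stack)
  out <- (v - q[1]) / (q[2] - q[1]) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  tomogram_stack(array(out, dim(v)), stack$px_size_xy,
                 stack$voxel_depth_z, stack$source_path)
}

#' Per-slice mean filter with a circular kernel
#'
#' Flat disk kernel containing every integer offset with
#' `dx^2 + dy^2 <= radius^2`; borders handled by edge replication.  Applied
#' slice-wise in 2D, matching how stack filters behave in common EM image
#' software (and avoiding kernels that span the anisotropic z axis).
#'
#' @inheritParams rescale_xy
#' @return The smoothed [tomogram_stack()].
#' @export
mean_filter <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "tomogram_stack"))
  out <- cpp_mean_filter_disk(stack$voxels, params$mean_radius_px)
  tomogram_stack(array(out, dim(stack$voxels)), stack$px_size_xy,
                 stack$voxel_depth_z, stack$source_path)
}

#' Per-slice bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is the normalized weighted
#' mean of its window with weight = spatial Gaussian x intensity-range
#' Gaussian.  Output values are convex combinations of input values, so no
#' over/undershoot is possible.
#'
#' @inheritParams rescale_xy
#' @return The filtered [tomogram_stack()].
#' @export
bilateral_filter <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "tomogram_stack"))
  out <- cpp_bilateral_filter(stack$voxels,
                              params$bilateral_spatial_sigma,
                              params$bilateral_range_sigma)
  tomogram_stack(array(out, dim(stack$voxels)), stack$px_size_xy,
                 stack$voxel_depth_z, stack$source_path)
}

#' Full preprocessing pipeline
#'
#' Fixed order: rescale to 1 nm/px, contrast stretch, mean filter,
#' bilateral filter.
#'
#' @inheritParams rescale_xy
#' @param verbose print stage messages.
#' @return The preprocessed [tomogram_stack()].
#' @export
preprocess_stack <- function(stack, params = preprocess_params(),
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("preprocess: rescale to ", params$target_px_nm, " nm/px")
  stack <- rescale_xy(stack, params)
  say("preprocess: contrast stretch (saturation ",
      params$saturation_fraction, ")")
  stack <- stretch_contrast(stack, params)
  say("preprocess: mean filter r = ", params$mean_radius_px, " px")
  stack <- mean_filter(stack, params)
  say("preprocess: bilateral filter")
  bilateral_filter(stack, params)
}
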