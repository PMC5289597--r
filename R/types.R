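# Domain containers.  All volumes are 3D arrays with dim = c(nz, ny, nx),
# i.e. voxels[z, y, x]; x = column, y = row, 0-based in all file formats.
# Physical calibration: px_size_xy nm/px in x and y, voxel_depth_z nm/slice.

#' Tomogram stack
#'
#' A calibrated 3D intensity volume.  Voxels are stored as a numeric array
#' indexed `[z, y, x]`; the physical position of voxel center `(z, y, x)`
#' (0-based) is `(x * px_size_xy, y * px_size_xy, z * voxel_depth_z)` nm.
#'
#' @param voxels numeric 3D array, dim `(nz, ny, nx)`.
#' @param px_size_xy nm per pixel in x and y (positive).
#' @param voxel_depth_z nm per slice (positive).
#' @param source_path provenance string.
#' @return An object of class `tomogram_stack`.
#' @export
tomogram_stack <- function(voxels, px_size_xy, voxel_depth_z,
                           source_path = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (z, y, x)")
  if (!all(dim(voxels) >= 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(px_size_xy) || length(px_size_xy) != 1L || px_size_xy <= 0)
    stop("px_size_xy must be a positive scalar")
  if (!is.numeric(voxel_depth_z) || length(voxel_depth_z) != 1L ||
      voxel_depth_z <= 0)
    stop("voxel_depth_z must be a positive scalar")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("intensities must be finite everywhere")
  structure(list(voxels = voxels, px_size_xy = px_size_xy,
                 voxel_depth_z = voxel_depth_z,
                 source_path = as.character(source_path)),
            class = "tomogram_stack")
}

#' @export
print.tomogram_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "tomogram_stack: %d x %d x %d (z,y,x), %.4g nm/px xy, %.4g nm/slice z\n",
    d[1], d[2], d[3], x$px_size_xy, x$voxel_depth_z))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary foreground stack
#'
#' @param mask logical 3D array, dim `(nz, ny, nx)`.
#' @param px_size_xy,voxel_depth_z calibration inherited from the source.
#' @return An object of class `binary_stack`.
#' @export
binary_stack <- function(mask, px_size_xy, voxel_depth_z) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array (z, y, x)")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(mask = mask, px_size_xy = px_size_xy,
                 voxel_depth_z = voxel_depth_z),
            class = "binary_stack")
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_stack: %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Labeled candidate stack
#'
#' Integer-labeled volume: 0 = background, k > 0 = candidate k.
#'
#' @param labels integer 3D array, dim `(nz, ny, nx)`.
#' @param px_size_xy,voxel_depth_z calibration inherited from the source.
#' @return An object of class `label_stack`.
#' @export
label_stack <- function(labels, px_size_xy, voxel_depth_z) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array (z, y, x)")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be >= 0")
  structure(list(labels = labels, px_size_xy = px_size_xy,
                 voxel_depth_z = voxel_depth_z),
            class = "label_stack")
}

#' @export
print.label_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_stack: %d x %d x %d (z,y,x), %d labels\n",
              d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' Number of distinct positive labels
#' @param labels a `label_stack`.
#' @return integer count.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_stack"))
  length(setdiff(unique(as.integer(labels$labels)), 0L))
}

#' Polygon region of interest
#'
#' A closed polygon on one slice.  Vertices are `(x, y)` pixel coordinates
#' (x = column, y = row, 0-based); the polygon is implicitly closed.
#'
#' @param slice_index 0-based z index.
#' @param vertices numeric matrix with columns x, y and >= 3 rows.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(slice_index, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must have two columns (x, y)")
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  if (anyNA(vertices) || !all(is.finite(vertices)))
    stop("vertices must be finite")
  if (abs(polygon_area(vertices)) < 1e-9)
    stop("polygon has zero area (collinear vertices?)")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  structure(list(slice_index = as.integer(slice_index), vertices = vertices),
            class = "polygon_roi")
}

# signed shoelace area (positive = counterclockwise in x-right/y-up sense)
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Distance map
#'
#' Per-voxel Euclidean distance (nm, at 1 nm/px working scale) to the
#' nearest background voxel; exactly zero on background.
#'
#' @param values numeric 3D array of nonnegative distances.
#' @param px_size_xy,voxel_depth_z calibration inherited from the source.
#' @return An object of class `distance_map`.
#' @export
distance_map <- function(values, px_size_xy, voxel_depth_z) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array (z, y, x)")
  if (any(values < 0)) stop("distances must be nonnegative")
  structure(list(values = values, px_size_xy = px_size_xy,
                 voxel_depth_z = voxel_depth_z),
            class = "distance_map")
}
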