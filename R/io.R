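# User-facing readers and writers: stacks, label maps, polygon ROIs and
# result tables.  All lengths in files are nm; all pixel coordinates are
# 0-based with x = column, y = row.

#' Read an image stack (MRC or multi-page TIFF)
#'
#' The format is detected from the file signature.  For MRC, the header
#' pixel size (interpreted as nm) is used as default calibration; explicit
#' arguments always override it.  TIFF carries no calibration, so both
#' values are required there.
#'
#' @param path file path.
#' @param px_size_xy nm per pixel in x and y (overrides any header value).
#' @param voxel_depth_z nm per slice (overrides any header value).
#' @return A [tomogram_stack()].
#' @export
read_stack <- function(path, px_size_xy = NULL, voxel_depth_z = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sig <- readBin(path, "raw", n = 4L)
  is_tiff <- length(sig) >= 4L &&
    (all(sig[1:3] == as.raw(c(0x49, 0x49, 0x2a))) ||
     all(sig[1:3] == as.raw(c(0x4d, 0x4d, 0x00))))
  if (is_tiff) {
    vol <- read_tiff(path)
    if (is.null(px_size_xy) || is.null(voxel_depth_z))
      stop("TIFF stacks carry no calibration: give px_size_xy and ",
           "voxel_depth_z")
    return(tomogram_stack(vol, px_size_xy, voxel_depth_z, path))
  }
  m <- read_mrc(path)
  px <- if (!is.null(px_size_xy)) px_size_xy else m$px_size_xy
  dz <- if (!is.null(voxel_depth_z)) voxel_depth_z else m$voxel_depth_z
  if (is.null(px) || is.na(px) || px <= 0 ||
      is.null(dz) || is.na(dz) || dz <= 0)
    stop("non-positive or missing calibration for ", path,
         "; pass px_size_xy / voxel_depth_z explicitly")
  tomogram_stack(m$voxels, px, dz, path)
}

#' Write an image stack
#'
#' @param stack a [tomogram_stack()].
#' @param path output path; format from extension unless given.
#' @param format `"auto"` (by extension), `"mrc"` or `"tiff"`.
#' @param dtype sample type for TIFF (`"float32"`, `"uint8"`, `"uint16"`)
#'   or MRC mode (`"float32"` -> mode 2, `"uint8"`/`"int16"` -> 0/1).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "mrc", "tiff"),
                        dtype = "float32") {
  stopifnot(inherits(stack, "tomogram_stack"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "mrc"
  }
  if (format == "mrc") {
    mode <- switch(dtype, float32 = 2L, int16 = 1L, uint8 = 0L,
                   stop("unsupported MRC dtype ", dtype))
    write_mrc(stack$voxels, path, stack$px_size_xy, stack$voxel_depth_z,
              mode = mode)
  } else {
    write_tiff(stack$voxels, path, dtype = dtype)
  }
  invisible(path)
}

#' Read a polygon ROI file
#'
#' Plain-text format: first line `slice <index>`, then one `x y` vertex per
#' line (0-based pixel coordinates, x = column).
#'
#' @param path file path.
#' @return A [polygon_roi()].
#' @export
read_polygon_roi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty ROI file: ", path)
  head_parts <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_parts) != 2L || head_parts[1] != "slice")
    stop("ROI file must start with 'slice <index>': ", path)
  slice <- as.integer(head_parts[2])
  if (is.na(slice) || slice < 0L) stop("bad slice index in ", path)
  if (length(lines) < 4L)
    stop("a polygon needs at least 3 vertices: ", path)
  verts <- do.call(rbind, lapply(lines[-1], function(l) {
    p <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(p) != 2L || anyNA(p)) stop("bad vertex line in ", path)
    p
  }))
  polygon_roi(slice, verts)
}

#' Write a polygon ROI file
#' @param roi a [polygon_roi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygon_roi <- function(roi, path) {
  stopifnot(inherits(roi, "polygon_roi"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("slice %d", roi$slice_index), con)
  writeLines(sprintf("%.10g %.10g", roi$vertices[, 1], roi$vertices[, 2]),
             con)
  invisible(path)
}

#' Column layout of the vesicle result table
#' @param n_neighbors neighbour count n.
#' @return character vector of column names (13 + n).
#' @export
result_columns <- function(n_neighbors) {
  c("label", "center_x_nm", "center_y_nm", "center_z_nm", "volume_nm3",
    "feret_nm", "diam1_nm", "diam2_nm", "diam3_nm", "mean_diam_nm",
    "corrected_diam_nm", "sphericity", "elongation",
    if (n_neighbors > 0) sprintf("dist_nn%d_nm", seq_len(n_neighbors)))
}

#' Write vesicle records to CSV
#'
#' All lengths are nm.  The table has 13 fixed columns plus one
#' `dist_nn<i>_nm` column per requested neighbour.
#'
#' @param records vesicle record data frame (see [measure_labels()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  n_nn <- attr(records, "n_neighbors")
  if (is.null(n_nn)) {
    nn_cols <- grep("^dist_nn\\d+_nm$", names(records), value = TRUE)
    n_nn <- length(nn_cols)
  }
  cols <- result_columns(n_nn)
  out <- as.data.frame(records)[, intersect(cols, names(records)),
                                drop = FALSE]
  for (mis in setdiff(cols, names(out)))
    out[[mis]] <- rep(NA_real_, nrow(out))
  out <- out[, cols, drop = FALSE]
  utils::write.csv(format_results_numeric(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# fixed-format numbers so identical runs give byte-identical files
format_results_numeric <- function(df) {
  for (nm in names(df)) {
    if (nm == "label") { df[[nm]] <- as.integer(df[[nm]]); next }
    v <- df[[nm]]
    df[[nm]] <- ifelse(is.na(v), "NA", sprintf("%.6f", v))
  }
  df
}

#' Read a vesicle result CSV written by [write_results()]
#' @param path file path.
#' @return data frame of records.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path)
  attr(df, "n_neighbors") <- length(grep("^dist_nn\\d+_nm$", names(df)))
  df
}

#' Write / read a label stack as multi-page TIFF
#'
#' 16-bit unsigned when the largest label fits, 32-bit otherwise.
#'
#' @param labels a [label_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(labels, path) {
  stopifnot(inherits(labels, "label_stack"))
  mx <- max(labels$labels)
  write_tiff(labels$labels, path,
             dtype = if (mx <= 65535L) "uint16" else "uint32")
  invisible(path)
}

#' @rdname write_label_stack
#' @param px_size_xy,voxel_depth_z calibration to attach on read.
#' @export
read_label_stack <- function(path, px_size_xy, voxel_depth_z) {
  vol <- read_tiff(path)
  storage.mode(vol) <- "integer"
  label_stack(vol, px_size_xy, voxel_depth_z)
}

#' Write / read a phantom ground-truth table
#' @param gt ground-truth data frame (id, center, inner/outer diameter,
#'   fused flag).
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path)
}
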