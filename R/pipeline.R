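# Pipeline orchestration: the two-stage workflow (register, then measure)
# plus simulate and evaluate, with run manifests for reproducibility.

#' Run the registration stage
#'
#' Preprocess, threshold, mask with the interpolated cell boundary, fill
#' holes, segment, measure, and apply the exclusion criteria.  ROI vertex
#' coordinates are interpreted on the *input* pixel grid and are scaled to
#' the 1 nm/px working grid internally.
#'
#' @param stack a [tomogram_stack()] or a file path.
#' @param roi_first,roi_last [polygon_roi()] objects or file paths.
#' @param px_size_xy,voxel_depth_z calibration (required when `stack` is a
#'   TIFF path; overrides headers otherwise).
#' @param criteria a [filter_criteria()] or preset name for
#'   [preset_criteria()].
#' @param pre_params,hole_params,seg_params,config stage parameter objects.
#' @param out_dir when non-NULL, writes `labels.tif`, `candidates.csv`,
#'   `composite.tif` and `manifest.json` there.
#' @param seed recorded in the manifest (the registration stage itself is
#'   deterministic).
#' @param verbose print per-stage progress.
#' @return A list: `labels` ([label_stack()]), `records` (candidate data
#'   frame), `preprocessed` ([tomogram_stack()]).
#' @export
run_register <- function(stack, roi_first, roi_last,
                         px_size_xy = NULL, voxel_depth_z = NULL,
                         criteria = "celegans",
                         pre_params = preprocess_params(),
                         hole_params = holefill_params(),
                         seg_params = segment_params(),
                         config = measure_config(),
                         out_dir = NULL, seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(stack))
    stack <- read_stack(stack, px_size_xy, voxel_depth_z)
  stopifnot(inherits(stack, "tomogram_stack"))
  if (is.character(roi_first)) roi_first <- read_polygon_roi(roi_first)
  if (is.character(roi_last)) roi_last <- read_polygon_roi(roi_last)
  if (is.character(criteria)) criteria <- preset_criteria(criteria)

  f <- stack$px_size_xy / pre_params$target_px_nm
  pre <- preprocess_stack(stack, pre_params, verbose = verbose)
  nz <- dim(pre$voxels)[1]
  roi_first <- polygon_roi(roi_first$slice_index, roi_first$vertices * f)
  roi_last <- polygon_roi(roi_last$slice_index, roi_last$vertices * f)
  if (roi_last$slice_index != nz - 1L)
    roi_last$slice_index <- nz - 1L
  rois <- interpolate_roi(roi_first, roi_last, nz)

  fg <- threshold_mean(pre)
  say("register: ", sum(fg$mask), " foreground voxels after threshold")
  fg <- apply_roi_mask(fg, rois)
  say("register: ", sum(fg$mask), " after ROI mask")
  fg <- fill_holes_bounded(fg, hole_params)
  say("register: ", sum(fg$mask), " after dilation + hole filling")
  labs <- segment_stack(fg, seg_params, verbose = verbose)
  records <- measure_labels(labs)
  say("register: ", nrow(records), " candidates before criteria")
  res <- apply_criteria(records, labs, criteria)
  labs <- res$labels
  records <- mean_and_corrected_diameter(res$records, config)
  say("register: ", nrow(records), " candidates after criteria")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_label_stack(labs, file.path(out_dir, "labels.tif"))
    attr(records, "n_neighbors") <- 0L
    write_results(records, file.path(out_dir, "candidates.csv"))
    write_stack(composite_stack(pre, labs),
                file.path(out_dir, "composite.tif"), dtype = "uint8")
    manifest <- list(
      stage = "register", package = "vesseg",
      version = as.character(utils::packageVersion("vesseg")),
      seed = seed, source = stack$source_path,
      px_size_xy = stack$px_size_xy, voxel_depth_z = stack$voxel_depth_z,
      criteria = unclass(criteria), preprocess = unclass(pre_params),
      holefill = unclass(hole_params), segment = unclass(seg_params))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(labels = labs, records = records, preprocessed = pre)
}

# overlay: preprocessed stack with one-pixel label contours burned to 255
composite_stack <- function(pre, labs) {
  m <- labs$labels > 0L
  inner <- array(cpp_erode_disk2d(m, 1), dim(m))
  v <- pre$voxels
  v[m & !inner] <- 255
  tomogram_stack(v, pre$px_size_xy, pre$voxel_depth_z, pre$source_path)
}

#' Run the measurement stage
#'
#' Applies an optional edit list (delete/merge), re-measures all labels,
#' computes neighbour distances and the membrane-corrected diameter.
#'
#' @param labels a [label_stack()], or a path to a label TIFF (calibration
#'   then from `manifest.json` next to it, or from the explicit
#'   arguments).
#' @param records candidate records matching `labels`; re-measured from
#'   the label stack when NULL.
#' @param edits character vector of edit directives, or a file path, or
#'   NULL.
#' @param config a [measure_config()].
#' @param px_size_xy,voxel_depth_z calibration when `labels` is a path.
#' @param out_dir when non-NULL, writes `vesicles.csv`,
#'   `labels_final.tif` and `manifest.json`.
#' @return A list: `labels`, `records` (final measured table).
#' @export
run_measure <- function(labels, records = NULL, edits = NULL,
                        config = measure_config(),
                        px_size_xy = NULL, voxel_depth_z = NULL,
                        out_dir = NULL) {
  if (is.character(labels)) {
    mpath <- file.path(dirname(labels), "manifest.json")
    if (is.null(px_size_xy) || is.null(voxel_depth_z)) {
      if (!file.exists(mpath))
        stop("no manifest.json next to ", labels,
             "; pass px_size_xy and voxel_depth_z")
      man <- jsonlite::read_json(mpath)
      px_size_xy <- if (is.null(px_size_xy))
        man$preprocess$target_px_nm else px_size_xy
      voxel_depth_z <- if (is.null(voxel_depth_z))
        man$voxel_depth_z else voxel_depth_z
    }
    labels <- read_label_stack(labels, px_size_xy, voxel_depth_z)
  }
  stopifnot(inherits(labels, "label_stack"))
  if (is.null(records)) records <- measure_labels(labels)
  if (!is.null(edits)) {
    if (length(edits) == 1L && file.exists(edits))
      edits <- readLines(edits, warn = FALSE)
    r <- apply_edits(labels, records, edits)
    labels <- r$labels
    records <- measure_labels(labels)  # re-measure after edits
  }
  records <- nearest_neighbor_distances(records, config)
  records <- mean_and_corrected_diameter(records, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(records, file.path(out_dir, "vesicles.csv"))
    write_label_stack(labels, file.path(out_dir, "labels_final.tif"))
    manifest <- list(stage = "measure", package = "vesseg",
                     version = as.character(utils::packageVersion("vesseg")),
                     n_neighbors = config$n_neighbors,
                     membrane_offset_nm = config$membrane_offset_nm)
    jsonlite::write_json(manifest, file.path(out_dir,
                                             "manifest_measure.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(labels = labels, records = records)
}

#' Generate a phantom and write it to disk
#'
#' @param params a [phantom_params()].
#' @param out_dir output directory.
#' @param format `"mrc"` or `"tiff"` for the stack.
#' @return The [generate_phantom()] result, invisibly.
#' @export
run_simulate <- function(params = phantom_params(), out_dir,
                         format = c("mrc", "tiff")) {
  format <- match.arg(format)
  ph <- generate_phantom(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(ph$stack, file.path(out_dir, paste0(
    "stack.", if (format == "mrc") "mrc" else "tif")), format = format)
  write_ground_truth(ph$gt, file.path(out_dir, "ground_truth.csv"))
  write_polygon_roi(ph$roi_first, file.path(out_dir, "roi_first.txt"))
  write_polygon_roi(ph$roi_last, file.path(out_dir, "roi_last.txt"))
  jsonlite::write_json(unclass(params), file.path(out_dir, "phantom.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(ph)
}

#' Evaluate predictions against ground truth
#'
#' @param truth ground-truth data frame or CSV path.
#' @param pred prediction records or CSV path.
#' @param max_dist_nm matching cutoff (see [match_detections()]).
#' @param out_dir when non-NULL, writes `metrics.csv` and `pairs.csv`.
#' @return The [match_detections()] result.
#' @export
run_evaluate <- function(truth, pred, max_dist_nm = NULL,
                         out_dir = NULL) {
  if (is.character(truth)) truth <- read_ground_truth(truth)
  if (is.character(pred)) pred <- read_results(pred)
  res <- match_detections(truth, pred, max_dist_nm)
  if (res$tp == 0L && nrow(truth) > 0 && nrow(pred) > 0)
    warning("no detection matched any ground-truth vesicle; ",
            "check that both tables use the same units (nm)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(tp = res$tp, fp = res$fp, fn = res$fn,
                                precision = res$precision,
                                recall = res$recall,
                                error_rate_pct = res$error_rate_pct),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(res$pairs, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
  }
  res
}
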