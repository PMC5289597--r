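# Detection quality against ground truth: optimal one-to-one center
# matching with a distance cutoff, precision / recall / error rate.

#' Match detections against ground truth
#'
#' One-to-one assignment between ground-truth vesicles and predicted
#' records minimizing total center distance among pairs closer than
#' `max_dist_nm` (optimal bipartite assignment, Jonker-Volgenant);
#' unmatched predictions count as false positives, unmatched ground truth
#' as false negatives.
#'
#' @param gt ground-truth data frame with `center_x_nm`, `center_y_nm`,
#'   `center_z_nm` (and optionally `id`).
#' @param pred predicted records with the same center columns (and
#'   optionally `label`).
#' @param max_dist_nm matching cutoff; defaults to half the mean
#'   ground-truth inner diameter when that column is present, else 20 nm.
#' @return A `match_result` list: `tp`, `fp`, `fn`, `pairs` (data frame
#'   gt_id, pred_label, center_dist_nm), `precision`, `recall`,
#'   `error_rate_pct`.
#' @export
match_detections <- function(gt, pred, max_dist_nm = NULL) {
  if (is.null(max_dist_nm)) {
    max_dist_nm <- if (!is.null(gt$inner_diameter_nm) &&
                       nrow(gt) > 0) mean(gt$inner_diameter_nm) / 2 else 20
  }
  stopifnot(max_dist_nm > 0)
  ng <- nrow(gt)
  np <- nrow(pred)
  gt_ids <- if (!is.null(gt$id)) gt$id else seq_len(ng)
  pr_ids <- if (!is.null(pred$label)) pred$label else seq_len(np)
  pairs <- data.frame(gt_id = integer(0), pred_label = integer(0),
                      center_dist_nm = numeric(0))
  tp <- 0L
  if (ng > 0 && np > 0) {
    G <- as.matrix(gt[, c("center_x_nm", "center_y_nm", "center_z_nm")])
    P <- as.matrix(pred[, c("center_x_nm", "center_y_nm", "center_z_nm")])
    D <- outer(seq_len(ng), seq_len(np), function(i, j)
      sqrt((G[i, 1] - P[j, 1])^2 + (G[i, 2] - P[j, 2])^2 +
           (G[i, 3] - P[j, 3])^2))
    # square matrix with dummy rows/cols so any node may stay unmatched:
    # unmatched penalty M1, forbidden (too-far) pairs cost > 2 * M1
    M1 <- 1e6
    n <- ng + np
    cost <- matrix(0, n, n)
    cost[seq_len(ng), seq_len(np)] <- ifelse(D <= max_dist_nm, D, 2.5 * M1)
    cost[seq_len(ng), np + seq_len(ng)] <- M1     # gt unmatched
    cost[ng + seq_len(np), seq_len(np)] <- M1     # pred unmatched
    a <- cpp_hungarian(cost)
    for (i in seq_len(ng)) {
      j <- a[i]
      if (j <= np && D[i, j] <= max_dist_nm) {
        tp <- tp + 1L
        pairs <- rbind(pairs, data.frame(gt_id = gt_ids[i],
                                         pred_label = pr_ids[j],
                                         center_dist_nm = D[i, j]))
      }
    }
  }
  fp <- np - tp
  fn <- ng - tp
  m <- metrics(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = m$precision, recall = m$recall,
                 error_rate_pct = m$error_rate_pct),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "match_result: TP %d, FP %d, FN %d | precision %.4f, recall %.4f, error %.2f%%\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$error_rate_pct))
  invisible(x)
}

#' Detection quality metrics
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `error_rate_pct = 100 * FN / (TP + FN)` (so recall =
#' 1 - error_rate/100 exactly).  Undefined ratios are reported as `NA`,
#' never as 0.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return A list with `precision`, `recall`, `error_rate_pct`.
#' @export
metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  error_rate_pct <- if (tp + fn > 0) 100 * fn / (tp + fn) else NA_real_
  list(precision = precision, recall = recall,
       error_rate_pct = error_rate_pct)
}
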