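#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary H x W matrices of equal shape.
#' @return list with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_forceseg("pred and truth shapes differ", "forceseg_shape_error")
  p <- pred > 0; y <- truth > 0
  list(tp = sum(p & y), fp = sum(p & !y), fn = sum(!p & y), tn = sum(!p & !y))
}

#' Region metrics from confusion counts
#'
#' Dice `2|A∩B|/(|A|+|B|)`, IoU `|A∩B|/|A∪B|`, precision, recall and their
#' harmonic mean F1. Conventions for degenerate inputs: both masks empty,
#' all metrics are 1; exactly one empty, all are 0.
#'
#' @param counts list with `tp`, `fp`, `fn`, `tn` (see [confusion()]).
#' @return named list `dice`, `iou`, `precision`, `recall`, `f1`.
#' @export
region_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0)
    return(list(dice = 1, iou = 1, precision = 1, recall = 1, f1 = 1))
  if (tp == 0 && (fp == 0 || fn == 0) && fp + fn > 0)
    return(list(dice = 0, iou = 0, precision = 0, recall = 0, f1 = 0))
  dice <- 2 * tp / (2 * tp + fp + fn)
  iou <- tp / (tp + fp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(dice = dice, iou = iou, precision = precision, recall = recall, f1 = f1)
}

#' Boundary F1 score within a pixel tolerance
#'
#' Boundary precision is the fraction of predicted boundary pixels within
#' `tolerance` (Euclidean) of any true boundary pixel; boundary recall is
#' symmetric; the BF score is their harmonic mean. Boundaries follow
#' [extract_boundary()]. Degenerate conventions match [region_metrics()]:
#' both masks empty gives 1, exactly one empty gives 0.
#'
#' @param pred,truth binary H x W matrices.
#' @param tolerance non-negative match distance in pixels (default 2).
#' @return scalar in `[0, 1]`.
#' @export
boundary_f1 <- function(pred, truth, tolerance = 2) {
  stopifnot(tolerance >= 0)
  if (!all(dim(pred) == dim(truth)))
    stop_forceseg("pred and truth shapes differ", "forceseg_shape_error")
  np <- sum(pred > 0); nt <- sum(truth > 0)
  if (np == 0 && nt == 0) return(1)
  if (np == 0 || nt == 0) return(0)
  bp <- extract_boundary(pred)
  bt <- extract_boundary(truth)
  dt <- boundary_distance_map(bt)
  dp <- boundary_distance_map(bp)
  bprec <- mean(dt[bp$points + 1L] <= tolerance)
  brec <- mean(dp[bt$points + 1L] <= tolerance)
  if (bprec + brec == 0) return(0)
  2 * bprec * brec / (bprec + brec)
}

#' Evaluate a collection of predictions against ground truth
#'
#' Per-image binary-foreground metrics (any positive label is foreground)
#' plus an unweighted mean row with id `"mean"`.
#'
#' @param pred_labels,truth_labels named lists of label maps (or binary
#'   masks); names are matched as image ids.
#' @param tolerance boundary F1 tolerance in pixels.
#' @param out_csv optional path; when given the table is written as CSV.
#' @return data.frame with columns `image_id`, `dice`, `iou`, `precision`,
#'   `recall`, `f1`, `bf`.
#' @export
evaluate_dataset <- function(pred_labels, truth_labels, tolerance = 2,
                             out_csv = NULL) {
  ids <- names(truth_labels)
  if (is.null(ids)) {
    ids <- as.character(seq_along(truth_labels))
    names(truth_labels) <- ids
    if (is.null(names(pred_labels))) names(pred_labels) <- ids
  }
  if (!setequal(names(pred_labels), ids))
    stop_forceseg("prediction and truth ids do not match",
                  "forceseg_id_mismatch")
  rows <- lapply(ids, function(id) {
    p <- (pred_labels[[id]] > 0) * 1
    y <- (truth_labels[[id]] > 0) * 1
    m <- region_metrics(confusion(p, y))
    data.frame(image_id = id, dice = m$dice, iou = m$iou,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               bf = boundary_f1(p, y, tolerance), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(image_id = "mean", t(colMeans(tab[, -1])),
                         stringsAsFactors = FALSE)
  out <- rbind(tab, mean_row)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
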