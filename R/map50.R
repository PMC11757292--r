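# Detection scoring: IoU matching and mean average precision at a fixed IoU
# threshold (mAP50 by default). Boxes are axis-aligned [x1, y1, x2, y2] in
# pixel coordinates with x2 > x1, y2 > y1.

#' Detection evaluation configuration
#'
#' @param iou_threshold Minimum intersection-over-union for a detection to
#'   match a ground-truth box (default 0.5, i.e. mAP50).
#' @return An object of class `detection_eval_config`.
#' @export
detection_eval_config <- function(iou_threshold = 0.5) {
  check_number(iou_threshold, "iou_threshold", min = 0, strict_min = TRUE)
  if (iou_threshold >= 1) stopf("'iou_threshold' must be < 1")
  structure(list(iou_threshold = iou_threshold), class = "detection_eval_config")
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Numeric length-4 vectors `(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area <- function(r) (r[3] - r[1]) * (r[4] - r[2])
  inter / (area(a) + area(b) - inter)
}

check_boxes_df <- function(df, name, need_score = FALSE) {
  need <- c("image", "class", "x1", "y1", "x2", "y2", if (need_score) "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("'%s' lacks column(s): %s", name, paste(missing_cols, collapse = ", "))
  if (nrow(df) && (any(df$x2 <= df$x1) || any(df$y2 <= df$y1)))
    stopf("'%s' contains degenerate boxes (x2 <= x1 or y2 <= y1)", name)
  invisible(df)
}

# All-point AP: area under the precision envelope as a function of recall.
ap_from_pr <- function(tp_flags, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp_flags) == 0) return(0)
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # envelope: precision at recall r is the max precision at any recall >= r
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Mean average precision at an IoU threshold
#'
#' Per class, detections are sorted by descending confidence and greedily
#' matched: each detection claims the not-yet-matched ground-truth box (same
#' image, same class) of highest IoU, provided that IoU reaches the
#' threshold; otherwise it counts as a false positive. AP is the area under
#' the all-point precision envelope over recall, and mAP the unweighted mean
#' over classes present in the ground truth.
#'
#' @param detections Data frame with columns `image`, `class`, `x1`, `y1`,
#'   `x2`, `y2`, `score`.
#' @param ground_truth Data frame with the same columns minus `score`.
#' @param config A [detection_eval_config()].
#' @return mAP in `[0, 1]`; `NA` if there is no ground truth at all.
#' @export
map50 <- function(detections, ground_truth, config = detection_eval_config()) {
  check_boxes_df(detections, "detections", need_score = TRUE)
  check_boxes_df(ground_truth, "ground_truth")
  if (nrow(ground_truth) == 0L) {
    warning("no ground-truth boxes: mAP undefined", call. = FALSE)
    return(NA_real_)
  }
  thr <- config$iou_threshold
  classes <- unique(ground_truth$class)
  aps <- vapply(classes, function(cl) {
    gt <- ground_truth[ground_truth$class == cl, , drop = FALSE]
    det <- detections[detections$class == cl, , drop = FALSE]
    det <- det[order(-det$score), , drop = FALSE]
    matched <- rep(FALSE, nrow(gt))
    tp_flags <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      cand <- which(gt$image == det$image[i] & !matched)
      if (!length(cand)) next
      ious <- vapply(cand, function(j)
        box_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                as.numeric(gt[j, c("x1", "y1", "x2", "y2")])), numeric(1))
      best <- which.max(ious)
      if (ious[best] >= thr) {
        matched[cand[best]] <- TRUE
        tp_flags[i] <- TRUE
      }
    }
    ap_from_pr(tp_flags, nrow(gt))
  }, numeric(1))
  mean(aps)
}
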