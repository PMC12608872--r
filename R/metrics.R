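# Detection evaluation: greedy IoU matching, precision/recall, average
# precision by all-points interpolation, and weather-stratified reporting.
#
# Boxes are 0-based, half-open pixel rectangles (x_min, y_min, x_max, y_max)
# throughout the package; detections and ground truths are data frames.

#' Construct detection and ground-truth tables
#'
#' @param x_min,y_min,x_max,y_max box coordinates (pixels, half-open).
#' @param conf detection confidence in `[0, 1]`.
#' @param class_id class label (default `"Phoca largha"`).
#' @param image_id frame identifier.
#' @return a data frame with one row per box.
#' @export
detections <- function(x_min, y_min, x_max, y_max, conf,
                       class_id = "Phoca largha", image_id = 1L) {
  d <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                  conf = conf, class_id = class_id, image_id = image_id,
                  stringsAsFactors = FALSE)
  validate_boxes(d)
  if (any(!is.finite(d$conf))) stop("confidences must be finite", call. = FALSE)
  d
}

#' @rdname detections
#' @export
ground_truth <- function(x_min, y_min, x_max, y_max,
                         class_id = "Phoca largha", image_id = 1L) {
  d <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                  class_id = class_id, image_id = image_id,
                  stringsAsFactors = FALSE)
  validate_boxes(d)
  d
}

validate_boxes <- function(d) {
  if (nrow(d) && any(d$x_min >= d$x_max | d$y_min >= d$y_max))
    stop("invalid box: requires x_min < x_max and y_min < y_max", call. = FALSE)
  invisible(d)
}

empty_detections <- function() detections(numeric(0), numeric(0), numeric(0),
                                          numeric(0), numeric(0),
                                          character(0), integer(0))

#' Intersection over union of two boxes
#'
#' @param a,b numeric vectors `c(x_min, y_min, x_max, y_max)`.
#' @return scalar in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# IoU matrix between detection and ground-truth tables
iou_matrix <- function(dets, gts) {
  m <- matrix(0, nrow(dets), nrow(gts))
  for (i in seq_len(nrow(dets))) for (j in seq_len(nrow(gts)))
    m[i, j] <- iou(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
                   as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")]))
  m
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties broken by input
#' order, so results are deterministic); each is matched to the unmatched
#' ground-truth box of the same image with the highest IoU, provided that IoU
#' reaches `iou_thr` (a true positive), otherwise it is a false positive.
#' Ground-truth boxes left unmatched are false negatives, so
#' `TP + FN = |gts|` always.
#'
#' @param dets detection data frame (see [detections()]); single class.
#' @param gts ground-truth data frame.
#' @param iou_thr matching IoU threshold in `(0, 1)`; 0.5 gives the usual
#'   mAP\@0.5 protocol.
#' @return list with `TP`, `FP`, `FN` and `labels`, a logical vector over
#'   detections in the original order (`TRUE` = true positive).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0L) return(list(TP = 0L, FP = 0L, FN = ng, labels = logical(0)))
  ord <- order(-dets$conf)
  labels <- logical(nd)
  matched <- logical(ng)
  m <- iou_matrix(dets, gts)
  for (i in ord) {
    cand <- which(!matched & gts$image_id == dets$image_id[i] &
                    gts$class_id == dets$class_id[i])
    if (!length(cand)) next
    j <- cand[which.max(m[i, cand])]
    if (m[i, j] >= iou_thr) {
      labels[i] <- TRUE
      matched[j] <- TRUE
    }
  }
  tp <- sum(labels)
  list(TP = tp, FP = nd - tp, FN = ng - tp, labels = labels)
}

#' Precision and recall from match counts
#'
#' Exact ratios `TP/(TP+FP)` and `TP/(TP+FN)`. The degenerate case of no
#' detections at all (`TP + FP = 0`) returns precision 1 by convention (no
#' claim made, none wrong -- the same convention used at the start of the
#' precision envelope); no ground truth (`TP + FN = 0`) returns recall 1.
#'
#' @param TP,FP,FN non-negative counts.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative", call. = FALSE)
  c(precision = if (TP + FP == 0) 1 else TP / (TP + FP),
    recall = if (TP + FN == 0) 1 else TP / (TP + FN))
}

#' Average precision over a confidence sweep
#'
#' Sorts detections by confidence, accumulates TP/FP counts, and integrates
#' the precision envelope over recall by all-points interpolation: precision
#' is first made monotone non-increasing from right to left, then the area
#' under the resulting step function is summed. AP depends only on the
#' confidence ranking, not on its scale.
#'
#' @inheritParams match_detections
#' @return a `pr_curve`: list with `precision`, `recall`, `conf` sequences,
#'   the match labels and the scalar `ap`.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5) {
  m <- match_detections(dets, gts, iou_thr)
  ng <- nrow(gts)
  ord <- order(-dets$conf)
  lab <- m$labels[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  prec <- tp / (tp + fp)
  rec <- if (ng > 0) tp / ng else rep(0, length(tp))
  structure(list(conf = dets$conf[ord], precision = prec, recall = rec,
                 labels = lab, ap = ap_from_pr(prec, rec)),
            class = "pr_curve")
}

# all-points interpolated area under the precision envelope
ap_from_pr <- function(precision, recall) {
  if (!length(recall)) return(0)
  r <- c(0, recall)
  p <- c(1, precision)
  # monotone non-increasing envelope from the right
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

#' Mean average precision
#'
#' Arithmetic mean of per-class average precisions; with a single class (the
#' spotted-seal setting) mAP equals that class's AP.
#'
#' @param per_class_aps numeric vector of per-class AP values.
#' @return scalar mAP.
#' @export
mean_average_precision <- function(per_class_aps) {
  if (!length(per_class_aps)) stop("need at least one class AP", call. = FALSE)
  mean(per_class_aps)
}

#' Aggregate metrics report
#'
#' @inheritParams match_detections
#' @return a list with counts, precision, recall and AP (equal to mAP in the
#'   single-class setting).
#' @export
metrics_report <- function(dets, gts, iou_thr = 0.5) {
  m <- match_detections(dets, gts, iou_thr)
  pr <- precision_recall(m$TP, m$FP, m$FN)
  curve <- average_precision(dets, gts, iou_thr)
  list(TP = m$TP, FP = m$FP, FN = m$FN,
       precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       ap = curve$ap, mAP = curve$ap, n_detections = nrow(dets))
}

#' Weather-stratified detection report
#'
#' Per-condition detection count, false-positive rate `FP/(TP+FP)` and
#' false-negative rate `FN/(TP+FN)` -- the rates used to compare detector
#' robustness across imaging conditions (sunny, reflective, foggy, overcast,
#' or any user-defined strata).
#'
#' @param batches named list; each element is `list(dets =, gts =)`.
#' @param iou_thr matching threshold.
#' @return data frame with one row per condition.
#' @export
condition_report <- function(batches, iou_thr = 0.5) {
  rows <- lapply(names(batches), function(cond) {
    b <- batches[[cond]]
    m <- match_detections(b$dets, b$gts, iou_thr)
    data.frame(condition = cond,
               n_detections = nrow(b$dets),
               TP = m$TP, FP = m$FP, FN = m$FN,
               fp_rate = if (m$TP + m$FP == 0) 0 else m$FP / (m$TP + m$FP),
               fn_rate = if (m$TP + m$FN == 0) 0 else m$FN / (m$TP + m$FN),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
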