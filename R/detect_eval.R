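#' Intersection over union of axis-aligned boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` in pixel units with
#' `x_min < x_max` and `y_min < y_max` (half-open or continuous corners;
#' only differences enter the areas).
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("degenerate (zero-area) box", call. = FALSE)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Greedy detection-to-ground-truth matching
#'
#' Detections (same image, same class) are processed in descending
#' confidence; each is matched to the unmatched ground-truth box of highest
#' IoU provided that IoU reaches the threshold, else it is a false
#' positive. Each ground truth is matched at most once. The default
#' threshold (0.5) is the ignore threshold used throughout the package's
#' evaluation.
#'
#' @param detections data.frame with columns `confidence` and `x_min`,
#'   `y_min`, `x_max`, `y_max` (zero rows allowed).
#' @param ground_truths data.frame with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @param iou_threshold minimum IoU for a match.
#' @return A list of class `match_result`: `tp` (logical per detection, in
#'   descending-confidence order), `order` (row indices of `detections` in
#'   that order), `gt_matched` (logical per ground truth), `iou_threshold`.
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.5) {
  nd <- nrow(detections)
  ng <- nrow(ground_truths)
  ord <- if (nd > 0) order(detections$confidence, decreasing = TRUE) else integer(0)
  tp <- logical(nd)
  gt_used <- logical(ng)
  for (k in seq_len(nd)) {
    d <- detections[ord[k], ]
    db <- c(d$x_min, d$y_min, d$x_max, d$y_max)
    best <- 0; best_j <- 0L
    for (j in seq_len(ng)) {
      if (gt_used[j]) next
      g <- ground_truths[j, ]
      ov <- box_iou(db, c(g$x_min, g$y_min, g$x_max, g$y_max))
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      tp[k] <- TRUE
      gt_used[best_j] <- TRUE
    }
  }
  structure(list(tp = tp, order = ord, gt_matched = gt_used,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' Average precision from confidence-ranked matches
#'
#' Builds the precision-recall curve from per-detection TP/FP flags in
#' descending-confidence order and integrates it. The default is the
#' all-point convention: AP is the area under the precision envelope
#' \eqn{\tilde p(r) = \max_{r' \ge r} p(r')} sampled at every recall change.
#' The 11-point interpolation (mean of the envelope at recalls
#' 0, 0.1, ..., 1) is available via `interpolation = "11point"`.
#'
#' @param tp logical vector, TP flag per detection, already sorted by
#'   descending confidence (across the whole dataset for one class).
#' @param n_ground_truth number of ground-truth boxes of this class
#'   (positive).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return A list of class `pr_curve`: `precision`, `recall` (cumulative
#'   arrays), `ap`.
#' @export
average_precision <- function(tp, n_ground_truth, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(n_ground_truth > 0)
  tp <- as.logical(tp)
  if (length(tp) == 0) {
    return(structure(list(precision = numeric(0), recall = numeric(0), ap = 0),
                     class = "pr_curve"))
  }
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(tp)
  recall <- ctp / n_ground_truth
  # precision envelope: running max from the right
  env <- rev(cummax(rev(precision)))
  ap <- if (interpolation == "all") {
    prev_r <- c(0, recall[-length(recall)])
    sum((recall - prev_r) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      keep <- recall >= r - 1e-12
      if (any(keep)) max(env[keep]) else 0
    }, numeric(1)))
  }
  structure(list(precision = precision, recall = recall, ap = ap),
            class = "pr_curve")
}

#' Evaluate detections against ground truth
#'
#' Computes per-class precision/recall at the detector's operating point
#' (all supplied detections count), average precision, and mAP (unweighted
#' mean over classes with at least one ground-truth box; classes without
#' ground truth are dropped with a warning).
#'
#' @param detections data.frame with columns `image`, `class`, `confidence`,
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @param ground_truths data.frame with columns `image`, `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @param iou_threshold IoU matching threshold (default the 0.5 ignore
#'   threshold).
#' @param interpolation AP flavour, see [average_precision()].
#' @return A list of class `detection_eval`: `per_class` data.frame
#'   (`class`, `n_gt`, `n_det`, `tp`, `fp`, `precision`, `recall`, `ap`) and
#'   `map` scalar.
#' @export
evaluate_detections <- function(detections, ground_truths,
                                iou_threshold = 0.5,
                                interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  classes <- sort(unique(ground_truths$class))
  skipped <- setdiff(unique(detections$class), classes)
  if (length(skipped) > 0) {
    warning("classes with no ground truth excluded from mAP: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (cl in classes) {
    det <- detections[detections$class == cl, , drop = FALSE]
    gt <- ground_truths[ground_truths$class == cl, , drop = FALSE]
    # match per image, then pool flags and re-sort by confidence
    conf <- numeric(0); flag <- logical(0)
    for (img in unique(c(det$image, gt$image))) {
      di <- det[det$image == img, , drop = FALSE]
      gi <- gt[gt$image == img, , drop = FALSE]
      if (nrow(di) == 0) next
      m <- match_detections(di, gi, iou_threshold)
      conf <- c(conf, di$confidence[m$order])
      flag <- c(flag, m$tp)
    }
    ord <- order(conf, decreasing = TRUE)
    flag <- flag[ord]
    pr <- average_precision(flag, nrow(gt), interpolation)
    ntp <- sum(flag)
    rows[[cl]] <- data.frame(
      class = cl, n_gt = nrow(gt), n_det = length(flag),
      tp = ntp, fp = length(flag) - ntp,
      precision = if (length(flag) > 0) ntp / length(flag) else NA_real_,
      recall = ntp / nrow(gt), ap = pr$ap)
  }
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  structure(list(per_class = per_class, map = mean(per_class$ap),
                 iou_threshold = iou_threshold),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU >= %.2f)\n", x$iou_threshold))
  df <- x$per_class
  df$precision <- round(100 * df$precision, 2)
  df$recall <- round(100 * df$recall, 2)
  df$ap <- round(100 * df$ap, 2)
  print(df, row.names = FALSE)
  cat(sprintf("mAP: %.2f%%\n", 100 * x$map))
  invisible(x)
}
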