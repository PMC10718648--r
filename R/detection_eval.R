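#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open pixel rectangles `(x_min, y_min, x_max,
#' y_max)`, so areas are exact products of side lengths. Returns 0 for
#' disjoint boxes; errors on zero-area boxes.
#'
#' @param a,b Numeric length-4 vectors `(x_min, y_min, x_max, y_max)` or
#'   one-row box tibbles.
#' @return IoU in `[0, 1]`; 1 iff the boxes are identical.
#' @export
iou <- function(a, b) {
  a <- as_box_vec(a); b <- as_box_vec(b)
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) {
    stop("degenerate box: zero area", call. = FALSE)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

as_box_vec <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    return(c(x$x_min, x$y_min, x$x_max, x$y_max))
  }
  stopifnot(is.numeric(x), length(x) == 4)
  x
}

# IoU matrix between two box tibbles (rows of a x rows of b), vectorized.
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  ax1 <- a$x_min; ay1 <- a$y_min; ax2 <- a$x_max; ay2 <- a$y_max
  bx1 <- b$x_min; by1 <- b$y_min; bx2 <- b$x_max; by2 <- b$y_max
  iw <- pmax(outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax), 0)
  ih <- pmax(outer(ay2, by2, pmin) - outer(ay1, by1, pmax), 0)
  inter <- iw * ih
  area_a <- (ax2 - ax1) * (ay2 - ay1)
  area_b <- (bx2 - bx1) * (by2 - by1)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Filter detections by confidence
#'
#' Keeps boxes with `confidence >= threshold`, preserving input order.
#'
#' @param detections Box tibble; every box must carry a confidence.
#' @param threshold Confidence threshold in `[0, 1]`.
#' @return Filtered box tibble.
#' @export
confidence_filter <- function(detections, threshold) {
  validate_boxes(detections, need_confidence = TRUE)
  detections[detections$confidence >= threshold, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Per image: sort detections by descending confidence (ties broken by
#' input order), repeatedly keep the top box and discard remaining boxes
#' of the same class (when `class_aware`) whose IoU with it exceeds
#' `iou_threshold`.
#'
#' @param detections Box tibble with confidences; multiple images are
#'   handled independently via `image_id`.
#' @param iou_threshold Overlap above which a lower-confidence duplicate
#'   is suppressed (default 0.45).
#' @param class_aware Only suppress within the same class (default TRUE).
#' @return Surviving boxes, in original input order.
#' @export
nms <- function(detections, iou_threshold = 0.45, class_aware = TRUE) {
  validate_boxes(detections, need_confidence = TRUE)
  if (nrow(detections) == 0) return(detections)
  keep_global <- logical(nrow(detections))
  for (img in unique(detections$image_id)) {
    idx <- which(detections$image_id == img)
    d <- detections[idx, , drop = FALSE]
    ord <- order(-d$confidence)       # stable: ties keep input order
    alive <- rep(TRUE, nrow(d))
    M <- iou_matrix(d, d)
    for (a in seq_along(ord)) {
      k <- ord[a]
      if (!alive[k]) next
      for (b in seq_along(ord)) {
        if (b <= a) next
        j <- ord[b]
        if (!alive[j]) next
        if (class_aware && d$class_id[j] != d$class_id[k]) next
        if (M[k, j] > iou_threshold) alive[j] <- FALSE
      }
    }
    keep_global[idx[alive]] <- TRUE
  }
  detections[keep_global, , drop = FALSE]
}

#' Greedy detection-to-ground-truth matching (one image, one class)
#'
#' Detections are processed in descending confidence (ties by input
#' order); each claims the so-far-unmatched ground truth with the highest
#' IoU at or above `iou_threshold` (IoU ties go to the lower ground-truth
#' index). Unmatched detections are false positives, unmatched ground
#' truths false negatives.
#'
#' @param dets,gts Box tibbles for a single image and single class; `dets`
#'   must carry confidences.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return Object of class `match_outcome`: counts `tp`, `fp`, `fn`, a
#'   `pairs` tibble (`det_index`, `gt_index`, `iou` - indices into the
#'   input tibbles), and `det_matched` (logical per detection, in
#'   descending-confidence processing order preserved back to input order).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  validate_boxes(dets, need_confidence = TRUE)
  validate_boxes(gts)
  if (length(unique(dets$class_id)) > 1 || length(unique(gts$class_id)) > 1) {
    stop("match_detections expects a single class; partition first",
         call. = FALSE)
  }
  M <- iou_matrix(dets, gts)
  ord <- order(-dets$confidence)
  gt_free <- rep(TRUE, nrow(gts))
  det_matched <- logical(nrow(dets))
  pairs <- list()
  for (k in ord) {
    if (!any(gt_free)) break
    ious <- M[k, ]
    ious[!gt_free] <- -Inf
    j <- which.max(ious)               # ties -> lowest index
    if (length(j) && ious[j] >= iou_threshold) {
      gt_free[j] <- FALSE
      det_matched[k] <- TRUE
      pairs[[length(pairs) + 1]] <-
        tibble::tibble(det_index = k, gt_index = j, iou = M[k, j])
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(det_index = integer(0), gt_index = integer(0),
                   iou = numeric(0))
  structure(list(tp = sum(det_matched),
                 fp = nrow(dets) - sum(det_matched),
                 fn = nrow(gts) - sum(det_matched),
                 pairs = pairs, det_matched = det_matched),
            class = "match_outcome")
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; each defined as 0 when its denominator is 0.
#'
#' @param tp,fp,fn Nonnegative counts (vectorized).
#' @return Tibble with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative",
                                   call. = FALSE)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble::tibble(precision = p, recall = r, f1 = f1)
}

# Per-detection TP flags for one class across a dataset, in global
# descending-confidence order. Returns tibble (confidence, tp_flag) plus
# the total ground-truth count.
class_detection_flags <- function(dets, gts, class_id, iou_threshold) {
  d <- dets[dets$class_id == class_id, , drop = FALSE]
  g <- gts[gts$class_id == class_id, , drop = FALSE]
  n_gt <- nrow(g)
  if (nrow(d) == 0) {
    return(list(flags = tibble::tibble(confidence = numeric(0),
                                       tp = logical(0)), n_gt = n_gt))
  }
  d$..row <- seq_len(nrow(d))
  tp <- logical(nrow(d))
  for (img in unique(d$image_id)) {
    di <- d[d$image_id == img, , drop = FALSE]
    gi <- g[g$image_id == img, , drop = FALSE]
    m <- match_detections(di, gi, iou_threshold)
    tp[di$..row] <- m$det_matched
  }
  ord <- order(-d$confidence)          # stable; ties keep input order
  list(flags = tibble::tibble(confidence = d$confidence[ord], tp = tp[ord]),
       n_gt = n_gt)
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence threshold over all detection scores (descending)
#' and accumulates TP/FP through greedy per-image matching.
#'
#' @param dets,gts Dataset-level box tibbles (multiple images via
#'   `image_id`); `dets` carry confidences.
#' @param class_id Severity class 1..9 to evaluate.
#' @param iou_threshold Match IoU (default 0.5).
#' @return Tibble `(confidence, precision, recall)`, one row per
#'   detection in descending confidence.
#' @export
pr_curve <- function(dets, gts, class_id, iou_threshold = 0.5) {
  cf <- class_detection_flags(dets, gts, class_id, iou_threshold)
  fl <- cf$flags
  ctp <- cumsum(fl$tp); cfp <- cumsum(!fl$tp)
  tibble::tibble(
    confidence = fl$confidence,
    precision = ifelse(ctp + cfp > 0, ctp / (ctp + cfp), 0),
    recall = if (cf$n_gt > 0) ctp / cf$n_gt else rep(0, nrow(fl))
  )
}

#' Average precision for one class
#'
#' Area under the precision envelope (precision made monotonically
#' non-increasing in recall), integrated over all recall change-points
#' ("all-point" interpolation).
#'
#' @inheritParams pr_curve
#' @return AP in `[0, 1]`; `NA` when the class has no ground truth
#'   (excluded from mAP); 0 when there are ground truths but no
#'   detections.
#' @export
average_precision <- function(dets, gts, class_id, iou_threshold = 0.5) {
  cf <- class_detection_flags(dets, gts, class_id, iou_threshold)
  if (cf$n_gt == 0) return(NA_real_)
  fl <- cf$flags
  if (nrow(fl) == 0) return(0)
  ctp <- cumsum(fl$tp); cfp <- cumsum(!fl$tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / cf$n_gt
  # monotone envelope from the right, then integrate over recall steps
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, head(rec, -1))
  sum((rec - r_prev) * env)
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class AP over the classes with at least one
#' ground-truth box; classes absent from the ground truth are excluded
#' from the mean.
#'
#' @param dets,gts Dataset-level box tibbles.
#' @param iou_threshold Match IoU (default 0.5).
#' @return mAP in `[0, 1]`.
#' @export
mean_ap <- function(dets, gts, iou_threshold = 0.5) {
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0) stop("no ground-truth classes", call. = FALSE)
  aps <- vapply(classes, function(cl)
    average_precision(dets, gts, cl, iou_threshold), 1.0)
  mean(aps)
}

#' mAP averaged over a range of IoU thresholds
#'
#' @param dets,gts Dataset-level box tibbles.
#' @param thresholds IoU thresholds; default 0.50 to 0.95 in steps of
#'   0.05 (ten values).
#' @return Mean of [mean_ap()] over the thresholds.
#' @export
map_range <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(t) mean_ap(dets, gts, t), 1.0))
}

#' Detection confusion matrix
#'
#' Class-agnostic greedy IoU matching after confidence filtering: within
#' each image, detections in descending confidence claim the unmatched
#' ground truth with highest IoU `>= iou_threshold` regardless of class.
#' A matched pair increments cell `(gt_class, det_class)`; an unmatched
#' ground truth increments `(gt_class, background)`; an unmatched
#' detection increments `(background, det_class)`.
#'
#' @param dets,gts Dataset-level box tibbles.
#' @param iou_threshold Match IoU (default 0.5).
#' @param conf_threshold Detections below this confidence are dropped
#'   first (default 0).
#' @return 10 x 10 integer matrix; rows = ground-truth class 1..9 plus
#'   `background`, columns = detected class 1..9 plus `background`.
#' @export
confusion_matrix <- function(dets, gts, iou_threshold = 0.5,
                             conf_threshold = 0) {
  validate_boxes(dets, need_confidence = TRUE)
  validate_boxes(gts)
  dets <- confidence_filter(dets, conf_threshold)
  lab <- c(as.character(1:9), "background")
  cm <- matrix(0L, 10, 10, dimnames = list(gt = lab, det = lab))
  images <- union(unique(gts$image_id), unique(dets$image_id))
  for (img in images) {
    d <- dets[dets$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    M <- iou_matrix(d, g)
    gt_free <- rep(TRUE, nrow(g))
    det_matched <- logical(nrow(d))
    for (k in order(-d$confidence)) {
      if (!any(gt_free)) break
      ious <- M[k, ]
      ious[!gt_free] <- -Inf
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_threshold) {
        gt_free[j] <- FALSE
        det_matched[k] <- TRUE
        cm[g$class_id[j], d$class_id[k]] <- cm[g$class_id[j],
                                               d$class_id[k]] + 1L
      }
    }
    for (j in which(gt_free)) cm[g$class_id[j], 10] <- cm[g$class_id[j],
                                                          10] + 1L
    for (k in which(!det_matched)) cm[10, d$class_id[k]] <- cm[10,
                                                  d$class_id[k]] + 1L
  }
  cm
}

#' F1 versus confidence threshold, micro-averaged over classes
#'
#' At each candidate threshold (the distinct detection confidences plus
#' 0), detections are filtered, matched per class and image, and TP/FP/FN
#' summed over the dataset before computing precision, recall and F1.
#'
#' @param dets,gts Dataset-level box tibbles.
#' @param iou_threshold Match IoU (default 0.5).
#' @return Tibble `(confidence, tp, fp, fn, precision, recall, f1)`.
#' @export
f1_curve <- function(dets, gts, iou_threshold = 0.5) {
  validate_boxes(dets, need_confidence = TRUE)
  thresholds <- sort(unique(c(0, dets$confidence)))
  rows <- lapply(thresholds, function(th) {
    d <- confidence_filter(dets, th)
    counts <- c(tp = 0, fp = 0, fn = 0)
    for (cl in sort(unique(c(d$class_id, gts$class_id)))) {
      for (img in union(unique(gts$image_id), unique(d$image_id))) {
        di <- d[d$class_id == cl & d$image_id == img, , drop = FALSE]
        gi <- gts[gts$class_id == cl & gts$image_id == img, , drop = FALSE]
        m <- match_detections(di, gi, iou_threshold)
        counts <- counts + c(m$tp, m$fp, m$fn)
      }
    }
    cbind(tibble::tibble(confidence = th, tp = counts[1], fp = counts[2],
                         fn = counts[3]),
          precision_recall_f1(counts[1], counts[2], counts[3]))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Full detection evaluation report
#'
#' Computes per-class AP and PR curves at `iou_threshold`, mAP at 0.5 and
#' averaged over 0.50-0.95, the micro-averaged F1-vs-confidence curve, the
#' class-agnostic confusion matrix, and per-class match counts at
#' `conf_threshold`.
#'
#' @param dets,gts Dataset-level box tibbles (`dets` with confidences).
#' @param iou_threshold Match IoU for AP, counts and the confusion matrix
#'   (default 0.5).
#' @param conf_threshold Confidence floor for the confusion matrix and the
#'   per-class counts (default 0).
#' @return Object of class `eval_report` with elements `per_class_ap`
#'   (tibble `class_id`, `ap`, `n_gt`, `tp`, `fp`, `fn`), `map50`,
#'   `map50_95`, `f1_curve`, `pr_curves` (tibble with `class_id`),
#'   `confusion`, `class_count`.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5,
                                conf_threshold = 0) {
  validate_boxes(dets, need_confidence = TRUE)
  validate_boxes(gts)
  classes <- sort(unique(gts$class_id))
  if (length(classes) == 0) stop("no ground-truth classes", call. = FALSE)
  d_conf <- confidence_filter(dets, conf_threshold)
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    counts <- c(tp = 0, fp = 0, fn = 0)
    for (img in union(unique(gts$image_id), unique(d_conf$image_id))) {
      di <- d_conf[d_conf$class_id == cl & d_conf$image_id == img, ,
                   drop = FALSE]
      gi <- gts[gts$class_id == cl & gts$image_id == img, , drop = FALSE]
      m <- match_detections(di, gi, iou_threshold)
      counts <- counts + c(m$tp, m$fp, m$fn)
    }
    tibble::tibble(class_id = cl,
                   ap = average_precision(dets, gts, cl, iou_threshold),
                   n_gt = sum(gts$class_id == cl),
                   tp = counts[1], fp = counts[2], fn = counts[3])
  }))
  curves <- dplyr::bind_rows(lapply(classes, function(cl) {
    dplyr::mutate(pr_curve(dets, gts, cl, iou_threshold), class_id = cl,
                  .before = 1)
  }))
  structure(
    list(per_class_ap = per_class,
         map50 = mean_ap(dets, gts, 0.5),
         map50_95 = map_range(dets, gts),
         f1_curve = f1_curve(dets, gts, iou_threshold),
         pr_curves = curves,
         confusion = confusion_matrix(dets, gts, iou_threshold,
                                      conf_threshold),
         class_count = length(classes)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classes | mAP@0.5 = %.4f | mAP@0.5:0.95 = %.4f\n",
              x$class_count, x$map50, x$map50_95))
  print(x$per_class_ap)
  invisible(x)
}
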