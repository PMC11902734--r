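# COCO-style evaluation: precision, recall, AP@50 and AP@50-95 for both
# bounding boxes and masks, per class and overall.

#' Intersection over union
#'
#' For two xyxy boxes (length-4 vectors) or two binary masks (matrices of
#' equal size): |intersection| / |union|; 0 for disjoint inputs, 1 for
#' identical ones; symmetric.
#'
#' @param a,b boxes or masks.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (length(a) > 4L || is.logical(a)) {
    stopifnot(all(dim(a) == dim(b)))
    ai <- a != 0; bi <- b != 0
    inter <- sum(ai & bi)
    uni <- sum(ai | bi)
    if (uni == 0) return(0)
    return(inter / uni)
  }
  ix <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  uni <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  if (uni <= 0) return(0)
  inter / uni
}

det_iou <- function(det, gt, mode) {
  if (mode == "box") iou(det$box, gt$box) else iou(det$mask, gt$mask)
}

#' Greedy detection-to-ground-truth matching
#'
#' Predictions are visited in descending score; each matches the
#' highest-IoU unmatched same-class ground truth with IoU at or above the
#' threshold (TP), otherwise it is a false positive. Each ground truth
#' matches at most once.
#'
#' @param preds list of detections (`class_id`, `score`, `box`, optional
#'   `mask`).
#' @param gts list of ground-truth objects with the same fields.
#' @param iou_thresh matching threshold.
#' @param mode "box" or "mask".
#' @return list: `$tp` logical flags in descending-score order, `$order`
#'   the corresponding indices into `preds`, `$scores`, `$classes`,
#'   `$n_gt` per-class ground-truth counts (named by 0-based class).
#' @export
match_detections <- function(preds, gts, iou_thresh = 0.5,
                             mode = c("box", "mask")) {
  mode <- match.arg(mode)
  k <- length(preds)
  scores <- vapply(preds, `[[`, 0, "score")
  ord <- order(-scores, seq_len(max(k, 1L))[seq_len(k)])
  gt_cls <- vapply(gts, `[[`, 0L, "class_id")
  used <- rep(FALSE, length(gts))
  tp <- logical(k)
  for (r in seq_len(k)) {
    i <- ord[r]
    p <- preds[[i]]
    js <- which(!used & gt_cls == p$class_id)
    if (!length(js)) next
    ious <- vapply(js, function(j) det_iou(p, gts[[j]], mode), 0)
    best <- which.max(ious)
    if (ious[best] >= iou_thresh) {
      tp[r] <- TRUE
      used[js[best]] <- TRUE
    }
  }
  ngt <- table(factor(gt_cls, levels = sort(unique(c(gt_cls, 0:1)))))
  list(tp = tp, order = ord, scores = scores[ord],
       classes = vapply(preds, `[[`, 0L, "class_id")[ord],
       n_gt = as.vector(ngt), n_gt_class = as.integer(names(ngt)))
}

#' 101-point interpolated average precision
#'
#' Builds the precision-recall curve from cumulative TP/FP flags (already
#' in descending-score order), applies monotone interpolation, and averages
#' precision at 101 evenly spaced recall points.
#'
#' @param tp logical flags, descending score.
#' @param n_gt number of ground-truth objects.
#' @return AP in `[0, 1]`; 0 when `n_gt == 0` and predictions exist;
#'   `NA` when there is nothing to evaluate.
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt == 0L) return(if (length(tp)) 0 else NA_real_)
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_gt
  # monotone (right-to-left running max) interpolation
  for (i in rev(seq_len(length(prec) - 1L)))
    prec[i] <- max(prec[i], prec[i + 1L])
  rpts <- seq(0, 1, by = 0.01)
  ap <- vapply(rpts, function(r) {
    j <- which(rec >= r)
    if (length(j)) prec[j[1L]] else 0
  }, 0)
  mean(ap)
}

# Pool flags for one class across images at one threshold.
pooled_flags <- function(dets_by_image, gts_by_image, class_id, iou_thresh,
                         mode) {
  scores <- numeric(0); tp <- logical(0); n_gt <- 0L
  for (i in seq_along(gts_by_image)) {
    gts <- Filter(function(g) g$class_id == class_id, gts_by_image[[i]])
    preds <- Filter(function(p) p$class_id == class_id,
                    if (i <= length(dets_by_image)) dets_by_image[[i]]
                    else list())
    n_gt <- n_gt + length(gts)
    if (!length(preds)) next
    m <- match_detections(preds, gts, iou_thresh, mode)
    scores <- c(scores, m$scores)
    tp <- c(tp, m$tp)
  }
  ord <- order(-scores, seq_along(scores))
  list(scores = scores[ord], tp = tp[ord], n_gt = n_gt)
}

#' Mean average precision over IoU 0.50 to 0.95
#'
#' AP at the ten thresholds 0.50, 0.55, ..., 0.95, averaged over thresholds
#' and then over classes.
#'
#' @param dets_by_image,gts_by_image per-image detection / ground-truth
#'   lists.
#' @param mode "box" or "mask".
#' @param classes 0-based class ids to evaluate.
#' @return scalar mAP@50-95.
#' @export
map_50_95 <- function(dets_by_image, gts_by_image, mode = "box",
                      classes = 0:1) {
  aps <- vapply(classes, function(cl) {
    per_thr <- vapply(seq(0.5, 0.95, by = 0.05), function(thr) {
      pf <- pooled_flags(dets_by_image, gts_by_image, cl, thr, mode)
      average_precision(pf$tp, pf$n_gt)
    }, 0)
    mean(per_thr)
  }, 0)
  mean(aps, na.rm = TRUE)
}

# gts_by_image as lists of {class_id, box, mask} built from image samples.
gt_objects <- function(sample, with_masks = TRUE) {
  d <- dim(sample$image)
  lapply(sample$instances, function(inst) {
    list(class_id = inst$class_id,
         box = inst$bbox * c(d[2L], d[1L], d[2L], d[1L]),
         mask = if (with_masks)
           polygon_to_mask(inst$polygon, d[1L], d[2L]) != 0L)
  })
}

#' Evaluate detections against ground truth
#'
#' Produces the full metric table per class and overall ("all" row is the
#' unweighted class mean): AP@50, AP@50-95, and precision/recall at the
#' per-class confidence that maximizes F1 (matching at IoU 0.5). Box and
#' mask modes are computed independently.
#'
#' @param dets_by_image per-image detection lists ([segment_image()]
#'   output), or a path to a COCO-results JSON file.
#' @param gt_samples list of [image_sample()] ground truth.
#' @param modes any of "box", "mask".
#' @return `eval_report`: named list of data.frames (one per mode) with
#'   columns class, precision, recall, ap50, ap50_95, n_gt.
#' @export
evaluate_detections <- function(dets_by_image, gt_samples,
                                modes = c("box", "mask")) {
  if (is.character(dets_by_image))
    dets_by_image <- read_coco_results(dets_by_image, length(gt_samples))
  want_mask <- "mask" %in% modes
  gts_by_image <- lapply(gt_samples, gt_objects, with_masks = want_mask)
  report <- list()
  for (mode in modes) {
    rows <- NULL
    for (cl in 0:1) {
      pf50 <- pooled_flags(dets_by_image, gts_by_image, cl, 0.5, mode)
      ap50 <- average_precision(pf50$tp, pf50$n_gt)
      ap5095 <- mean(vapply(seq(0.5, 0.95, by = 0.05), function(thr) {
        pf <- pooled_flags(dets_by_image, gts_by_image, cl, thr, mode)
        average_precision(pf$tp, pf$n_gt)
      }, 0))
      pr <- best_f1_point(pf50)
      rows <- rbind(rows, data.frame(
        class = CLASS_NAMES[cl + 1L], precision = pr[["precision"]],
        recall = pr[["recall"]], ap50 = ap50, ap50_95 = ap5095,
        n_gt = pf50$n_gt))
    }
    all_row <- data.frame(class = "all",
                          precision = mean(rows$precision, na.rm = TRUE),
                          recall = mean(rows$recall, na.rm = TRUE),
                          ap50 = mean(rows$ap50, na.rm = TRUE),
                          ap50_95 = mean(rows$ap50_95, na.rm = TRUE),
                          n_gt = sum(rows$n_gt))
    report[[mode]] <- rbind(all_row, rows)
  }
  structure(report, class = "eval_report")
}

best_f1_point <- function(pf) {
  if (!length(pf$tp) || pf$n_gt == 0L)
    return(c(precision = 0, recall = 0))
  ctp <- cumsum(pf$tp); cfp <- cumsum(!pf$tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / pf$n_gt
  f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
  i <- which.max(f1)
  c(precision = prec[i], recall = rec[i])
}

#' @export
print.eval_report <- function(x, ...) {
  for (mode in names(x)) {
    cat(sprintf("== %s ==\n", mode))
    df <- x[[mode]]
    cat(sprintf("%-8s %9s %9s %9s %9s %6s\n", "class", "precision",
                "recall", "mAP@50", "mAP@50-95", "n_gt"))
    for (i in seq_len(nrow(df)))
      cat(sprintf("%-8s %9.3f %9.3f %9.3f %9.3f %6d\n", df$class[i],
                  df$precision[i], df$recall[i], df$ap50[i],
                  df$ap50_95[i], df$n_gt[i]))
  }
  invisible(x)
}
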