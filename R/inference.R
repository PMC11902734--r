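# Prediction decoding, non-maximum suppression, and prototype mask
# assembly: raw network outputs to per-instance boxes, scores and binary
# masks.

#' Decode raw predictions into scored box candidates
#'
#' Each anchor's box is its center point offset by the expected value of
#' the per-side bin distribution times the scale stride; scores are
#' per-class sigmoids. One candidate is emitted per (class, anchor) pair
#' with score at or above the confidence threshold; masks are not yet
#' assembled.
#'
#' @param preds `raw_predictions` from [model_forward()].
#' @param conf_threshold minimum class score.
#' @param image batch index.
#' @return list of vectors/matrices: `$boxes` (4 x K, xyxy pixels at input
#'   scale), `$scores`, `$classes` (0-based), `$coef` (n_prototypes x K).
#' @export
decode_predictions <- function(preds, conf_threshold = 0.25, image = 1L) {
  anchors <- make_anchors(preds$input_size, preds$strides)
  fl <- flatten_preds(preds, image)
  dec <- decode_distances(fl$box, fl$reg_max)
  pbox <- boxes_from_distances(dec$dist, anchors)
  scores <- sigmoid(fl$cls)
  nc <- nrow(scores)
  boxes <- NULL; sc <- numeric(0); cls <- integer(0); coef <- NULL
  for (k in seq_len(nc)) {
    sel <- which(scores[k, ] >= conf_threshold)
    if (!length(sel)) next
    boxes <- cbind(boxes, pbox[, sel, drop = FALSE])
    sc <- c(sc, scores[k, sel])
    cls <- c(cls, rep(k - 1L, length(sel)))
    coef <- cbind(coef, fl$coef[, sel, drop = FALSE])
  }
  list(boxes = if (is.null(boxes)) matrix(0, 4L, 0L) else boxes,
       scores = sc, classes = cls,
       coef = if (is.null(coef)) matrix(0, dim(preds$proto)[1L], 0L)
              else coef)
}

#' Greedy class-wise non-maximum suppression
#'
#' Candidates are visited in descending score (ties broken by lower
#' candidate index); each survivor suppresses later same-class candidates
#' whose IoU with it exceeds the threshold.
#'
#' @param boxes 4 x K matrix (xyxy).
#' @param scores,classes length-K vectors.
#' @param iou_threshold suppression threshold.
#' @return indices of survivors, in descending-score order.
#' @export
nms <- function(boxes, scores, classes, iou_threshold = 0.7) {
  k <- length(scores)
  if (k == 0L) return(integer(0))
  ord <- order(-scores, seq_len(k))
  alive <- rep(TRUE, k)
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    same <- alive & classes == classes[i]
    same[i] <- FALSE
    if (any(same)) {
      ious <- iou_box_vec(boxes[, i], boxes[, same, drop = FALSE])
      alive[which(same)[ious > iou_threshold]] <- FALSE
    }
  }
  keep
}

#' Assemble a binary instance mask from prototype coefficients
#'
#' The mask logit is the linear combination of the prototype maps; its
#' sigmoid is bilinearly upsampled to the output size and thresholded at
#' 0.5 (>= 0.5 is foreground), then zeroed outside the detection box.
#'
#' @param coefficients length-n_prototypes vector.
#' @param prototypes (n_prototypes, Hp, Wp) array.
#' @param box xyxy pixel box at the output scale.
#' @param out_size output size: a scalar side length or c(height, width).
#' @return logical matrix (height x width).
#' @export
assemble_mask <- function(coefficients, prototypes, box, out_size) {
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  d <- dim(prototypes)
  pm <- matrix(prototypes, d[1L], d[2L] * d[3L])
  logit <- as.vector(crossprod(pm, coefficients))
  prob <- array(sigmoid(logit), c(1L, d[2L], d[3L]))
  up <- bilinear_resize(prob, out_size[1L], out_size[2L])
  mask <- matrix(up[1L, , ] >= 0.5, out_size[1L], out_size[2L])
  x1 <- max(1L, floor(box[1L]) + 1L); x2 <- min(out_size[2L], ceiling(box[3L]))
  y1 <- max(1L, floor(box[2L]) + 1L); y2 <- min(out_size[1L], ceiling(box[4L]))
  out <- matrix(FALSE, out_size[1L], out_size[2L])
  if (x2 >= x1 && y2 >= y1)
    out[y1:y2, x1:x2] <- mask[y1:y2, x1:x2]
  out
}

#' Segment a single image
#'
#' Full inference pipeline: square resize, forward pass, candidate
#' decoding, class-wise NMS, prototype mask assembly, and mapping of boxes
#' and masks back to the original raster geometry.
#'
#' @param model a trained `seg_model`.
#' @param raster H x W x 3 array in `[0, 1]`.
#' @param conf confidence threshold.
#' @param iou NMS IoU threshold.
#' @param max_det survivor cap.
#' @param with_masks assemble masks (disable for box-only evaluation).
#' @return list of detections, each `list(class_id, score, box, mask)` with
#'   `box` an xyxy pixel box and `mask` a logical H x W matrix (or `NULL`).
#' @export
segment_image <- function(model, raster, conf = 0.25, iou = 0.7,
                          max_det = 300L, with_masks = TRUE) {
  d <- dim(raster)
  sz <- model$spec$input_size
  chw <- aperm(raster, c(3L, 1L, 2L))
  x <- bilinear_resize(chw, sz, sz)
  dim(x) <- c(3L, sz, sz, 1L)
  preds <- model_forward(model, x, training = FALSE)
  cands <- decode_predictions(preds, conf)
  keep <- nms(cands$boxes, cands$scores, cands$classes, iou)
  keep <- head(keep, max_det)
  sx <- d[2L] / sz; sy <- d[1L] / sz
  proto <- array(preds$proto[, , , 1L], dim(preds$proto)[1:3])
  out <- list()
  for (i in keep) {
    b <- cands$boxes[, i]
    box <- c(max(0, b[1L] * sx), max(0, b[2L] * sy),
             min(d[2L], b[3L] * sx), min(d[1L], b[4L] * sy))
    if (box[3L] - box[1L] < 1 || box[4L] - box[2L] < 1) next
    mask <- NULL
    if (with_masks)
      mask <- assemble_mask(cands$coef[, i], proto, box,
                            c(d[1L], d[2L]))
    out <- c(out, list(list(class_id = cands$classes[i],
                            score = cands$scores[i],
                            box = box, mask = mask)))
  }
  out
}

# ---- COCO-results interchange ---------------------------------------------

# Uncompressed COCO run-length encoding of a logical mask
# (column-major, counts alternate background/foreground starting with
# background).
rle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(c(v))
  counts <- r$lengths
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(size = dim(mask), counts = as.integer(counts))
}

rle_decode <- function(rle) {
  vals <- rep(rep(c(0L, 1L), length.out = length(rle$counts)),
              rle$counts)
  matrix(vals == 1L, rle$size[1L], rle$size[2L])
}

#' Write / read detections as COCO-results JSON
#'
#' One record per detection: image_id, category_id (1-based), bbox
#' `[x, y, w, h]`, score, and an uncompressed RLE segmentation when masks
#' are present.
#'
#' @param dets_by_image list (per image) of detection lists from
#'   [segment_image()].
#' @param path output JSON path.
#' @return the path, invisibly; `read_coco_results()` returns the nested
#'   detection list.
#' @export
write_coco_results <- function(dets_by_image, path) {
  recs <- list()
  for (i in seq_along(dets_by_image)) {
    for (dt in dets_by_image[[i]]) {
      rec <- list(image_id = i, category_id = dt$class_id + 1L,
                  bbox = c(dt$box[1L], dt$box[2L],
                           dt$box[3L] - dt$box[1L],
                           dt$box[4L] - dt$box[2L]),
                  score = dt$score)
      if (!is.null(dt$mask)) rec$segmentation <- rle_encode(dt$mask)
      recs <- c(recs, list(rec))
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_results
#' @param n_images total image count (ids beyond the last detection keep
#'   empty slots).
#' @export
read_coco_results <- function(path, n_images = NULL) {
  recs <- jsonlite::read_json(path)
  ids <- vapply(recs, function(r) r$image_id, 1)
  n <- if (is.null(n_images)) max(c(ids, 0)) else n_images
  out <- rep(list(list()), n)
  for (r in recs) {
    bb <- unlist(r$bbox)
    det <- list(class_id = r$category_id - 1L, score = r$score,
                box = c(bb[1L], bb[2L], bb[1L] + bb[3L], bb[2L] + bb[4L]),
                mask = if (!is.null(r$segmentation))
                  rle_decode(list(size = unlist(r$segmentation$size),
                                  counts = unlist(r$segmentation$counts))))
    out[[r$image_id]] <- c(out[[r$image_id]], list(det))
  }
  out
}
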