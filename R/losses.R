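# Target assignment and the four-component detection/segmentation loss:
# CIoU box loss, binary cross-entropy classification, distribution focal
# loss over box-side bins, and per-pixel mask loss against assembled
# prototype masks. Gradients w.r.t. every raw prediction map are derived
# here and fed to the network's backward pass.

#' Training configuration
#'
#' Optimizer defaults follow the published regime: SGD with momentum 0.937,
#' weight decay 0.0005, initial learning rate 0.01, up to 500 epochs with
#' early stopping after 100 non-improving validation epochs. Loss weights
#' and assignment hyperparameters follow the reference single-stage
#' detector conventions.
#'
#' @param epochs,patience training length and early-stop patience.
#' @param momentum,weight_decay,lr0 SGD hyperparameters.
#' @param lrf final learning-rate fraction of the cosine schedule.
#' @param warmup_epochs linear warmup length.
#' @param batch_size images per gradient step.
#' @param box,cls,dfl,mask loss-component weights.
#' @param mosaic,fliplr,flipud,pixel_shift augmentation toggles.
#' @param dropout_rate coarse-cutout augmentation rate in [0, 1).
#' @param topk,alpha,beta task-aligned assigner hyperparameters
#'   (top-k anchors per target, classification and IoU exponents).
#' @param seed RNG seed for shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 500L, patience = 100L, momentum = 0.937,
                         weight_decay = 5e-4, lr0 = 0.01, lrf = 0.01,
                         warmup_epochs = 3L, batch_size = 8L,
                         box = 7.5, cls = 0.5, dfl = 1.5, mask = 1.0,
                         mosaic = TRUE, fliplr = TRUE, flipud = FALSE,
                         pixel_shift = TRUE, dropout_rate = 0,
                         topk = 10L, alpha = 0.5, beta = 6.0, seed = 0L) {
  stopifnot(epochs >= 1L, patience >= 0L, momentum >= 0, weight_decay >= 0,
            lr0 > 0, batch_size >= 1L, box >= 0, cls >= 0, dfl >= 0,
            mask >= 0, dropout_rate >= 0, dropout_rate < 1)
  structure(as.list(environment()), class = "train_config")
}

# Stable binary cross-entropy from logits. Logits are clamped so that
# extreme eval-mode activations (e.g. barely-initialized running batch-norm
# statistics) cannot produce Inf * 0 artifacts.
bce_logits <- function(z, t) {
  z <- pmin(pmax(z, -60), 60)
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# Anchor centers for every scale, pooled; linear anchor order within a
# scale is h + H*w (column-major, matching flattened feature maps).
make_anchors <- function(input_size, strides) {
  out <- lapply(strides, function(st) {
    g <- input_size %/% st
    h <- rep(seq_len(g) - 1L, times = g)
    w <- rep(seq_len(g) - 1L, each = g)
    list(ax = (w + 0.5) * st, ay = (h + 0.5) * st,
         stride = rep(st, g * g), g = g)
  })
  list(ax = unlist(lapply(out, `[[`, "ax")),
       ay = unlist(lapply(out, `[[`, "ay")),
       stride = unlist(lapply(out, `[[`, "stride")),
       per_scale = vapply(out, function(o) length(o$ax), 0L))
}

# Flatten one image's raw predictions across scales.
flatten_preds <- function(preds, n) {
  rm <- dim(preds$scales[[1L]]$box)[1L] %/% 4L
  nc <- dim(preds$scales[[1L]]$cls)[1L]
  npr <- dim(preds$scales[[1L]]$coef)[1L]
  box <- cls <- coef <- NULL
  for (sc in preds$scales) {
    a <- dim(sc$box)[2L] * dim(sc$box)[3L]
    box <- cbind(box, matrix(sc$box[, , , n], 4L * rm, a))
    cls <- cbind(cls, matrix(sc$cls[, , , n], nc, a))
    coef <- cbind(coef, matrix(sc$coef[, , , n], npr, a))
  }
  list(box = box, cls = cls, coef = coef, reg_max = rm)
}

# Distribution expectation decoding: per-side softmax over reg_max bins.
decode_distances <- function(box_flat, reg_max) {
  a <- ncol(box_flat)
  m <- matrix(box_flat, reg_max, 4L * a)
  mx <- m[1L, ]
  for (i in seq_len(reg_max)[-1L]) mx <- pmax(mx, m[i, ])
  e <- exp(m - rep(mx, each = reg_max))
  probs <- e / rep(colSums(e), each = reg_max)
  bins <- seq_len(reg_max) - 1
  dist <- matrix(colSums(probs * bins), 4L, a)
  list(dist = dist, probs = array(probs, c(reg_max, 4L, a)))
}

boxes_from_distances <- function(dist, anchors) {
  rbind(anchors$ax - dist[1L, ] * anchors$stride,
        anchors$ay - dist[2L, ] * anchors$stride,
        anchors$ax + dist[3L, ] * anchors$stride,
        anchors$ay + dist[4L, ] * anchors$stride)
}

# IoU of one box against columns of a 4 x n matrix (xyxy).
iou_box_vec <- function(b, m) {
  ix <- pmax(0, pmin(b[3L], m[3L, ]) - pmax(b[1L], m[1L, ]))
  iy <- pmax(0, pmin(b[4L], m[4L, ]) - pmax(b[2L], m[2L, ]))
  inter <- ix * iy
  a1 <- (b[3L] - b[1L]) * (b[4L] - b[2L])
  a2 <- (m[3L, ] - m[1L, ]) * (m[4L, ] - m[2L, ])
  inter / pmax(a1 + a2 - inter, 1e-9)
}

# Complete IoU of prediction columns p against matching gt columns g.
ciou_vec <- function(p, g) {
  ix <- pmax(0, pmin(p[3L, ], g[3L, ]) - pmax(p[1L, ], g[1L, ]))
  iy <- pmax(0, pmin(p[4L, ], g[4L, ]) - pmax(p[2L, ], g[2L, ]))
  inter <- ix * iy
  w1 <- p[3L, ] - p[1L, ]; h1 <- p[4L, ] - p[2L, ]
  w2 <- g[3L, ] - g[1L, ]; h2 <- g[4L, ] - g[2L, ]
  uni <- pmax(w1 * h1 + w2 * h2 - inter, 1e-9)
  iou <- inter / uni
  cw <- pmax(p[3L, ], g[3L, ]) - pmin(p[1L, ], g[1L, ])
  ch <- pmax(p[4L, ], g[4L, ]) - pmin(p[2L, ], g[2L, ])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- ((p[1L, ] + p[3L, ]) - (g[1L, ] + g[3L, ]))^2 / 4 +
    ((p[2L, ] + p[4L, ]) - (g[2L, ] + g[4L, ]))^2 / 4
  v <- (4 / pi^2) * (atan(w2 / pmax(h2, 1e-9)) -
                       atan(w1 / pmax(h1, 1e-9)))^2
  alpha <- v / pmax(1 - iou + v, 1e-9)
  iou - rho2 / c2 - alpha * v
}

#' Task-aligned target assignment
#'
#' Every ground truth claims its top-k in-box anchors by alignment score
#' `p_cls^alpha * IoU^beta` (classification probability of the target's
#' class times IoU of the currently decoded box); anchors claimed by several
#' targets go to the highest-scoring one.
#'
#' @param preds `raw_predictions` from [model_forward()].
#' @param instances list of [instance_annotation()] for one image.
#' @param image batch index to assign.
#' @param topk,alpha,beta assigner hyperparameters.
#' @param anchors,fl,dec optional precomputed anchor grid, flattened
#'   predictions and decoded distances (recomputed when `NULL`).
#' @return list with `$assign` (anchor-length vector, 0 = background, else
#'   ground-truth index), `$anchors`, `$gt_boxes` (4 x G pixel matrix),
#'   `$gt_class`, `$pred_boxes`, `$scores`.
#' @export
assign_targets <- function(preds, instances, image = 1L, topk = 10L,
                           alpha = 0.5, beta = 6.0, anchors = NULL,
                           fl = NULL, dec = NULL) {
  if (is.null(anchors)) anchors <- make_anchors(preds$input_size,
                                                preds$strides)
  if (is.null(fl)) fl <- flatten_preds(preds, image)
  if (is.null(dec)) dec <- decode_distances(fl$box, fl$reg_max)
  pbox <- boxes_from_distances(dec$dist, anchors)
  a <- length(anchors$ax)
  g <- length(instances)
  assign <- integer(a)
  scores <- matrix(0, max(g, 1L), a)
  if (g > 0L) {
    gtb <- vapply(instances, function(i) i$bbox * preds$input_size,
                  numeric(4L))
    gtc <- vapply(instances, function(i) i$class_id, 0L)
    pcls <- sigmoid(fl$cls)
    cand <- matrix(FALSE, g, a)
    for (j in seq_len(g)) {
      inb <- anchors$ax > gtb[1L, j] & anchors$ax < gtb[3L, j] &
        anchors$ay > gtb[2L, j] & anchors$ay < gtb[4L, j]
      iou <- iou_box_vec(gtb[, j], pbox)
      sc <- (pcls[gtc[j] + 1L, ]^alpha) * (iou^beta)
      sc[!inb] <- 0
      scores[j, ] <- sc
      ord <- order(sc, decreasing = TRUE)
      top <- ord[seq_len(min(topk, sum(inb)))]
      cand[j, top[sc[top] > 0]] <- TRUE
    }
    for (i in seq_len(a)) {
      js <- which(cand[, i])
      if (length(js))
        assign[i] <- js[which.max(scores[js, i])]
    }
    return(list(assign = assign, anchors = anchors, gt_boxes = gtb,
                gt_class = gtc, pred_boxes = pbox, scores = scores))
  }
  list(assign = assign, anchors = anchors,
       gt_boxes = matrix(0, 4L, 0L), gt_class = integer(0),
       pred_boxes = pbox, scores = scores)
}

#' Loss breakdown
#'
#' @param box,cls,dfl,mask non-negative component values.
#' @param weights named weight list/vector.
#' @return a `loss_breakdown` with `$total` the exact weighted sum.
#' @export
loss_breakdown <- function(box, cls, dfl, mask,
                           weights = c(box = 7.5, cls = 0.5, dfl = 1.5,
                                       mask = 1.0)) {
  stopifnot(box >= 0, cls >= 0, dfl >= 0, mask >= 0)
  structure(list(box = box, cls = cls, dfl = dfl, mask = mask,
                 weights = weights,
                 total = weights[["box"]] * box + weights[["cls"]] * cls +
                   weights[["dfl"]] * dfl + weights[["mask"]] * mask),
            class = "loss_breakdown")
}

# Ground-truth pack for one image: boxes, classes, proto-resolution masks.
gt_pack <- function(instances, input_size, proto_hw) {
  g <- length(instances)
  boxes <- if (g) vapply(instances, function(i) i$bbox * input_size,
                         numeric(4L)) else matrix(0, 4L, 0L)
  cls <- vapply(instances, function(i) i$class_id, integer(1))
  masks <- if (g)
    vapply(instances, function(i)
      as.numeric(polygon_to_mask(i$polygon, proto_hw, proto_hw)),
      numeric(proto_hw * proto_hw))
  else matrix(0, proto_hw * proto_hw, 0L)
  list(boxes = boxes, cls = cls, masks = masks, n = g)
}

# The full four-component loss over a batch, with optional gradients
# w.r.t. every raw prediction map.
detection_loss <- function(preds, gt_list, cfg = train_config(),
                           want_grads = FALSE) {
  anchors <- make_anchors(preds$input_size, preds$strides)
  a <- length(anchors$ax)
  nimg <- preds$n
  proto_hw <- dim(preds$proto)[2L]
  npr <- dim(preds$proto)[1L]
  nc <- dim(preds$scales[[1L]]$cls)[1L]
  reg_max <- dim(preds$scales[[1L]]$box)[1L] %/% 4L
  w <- c(box = cfg$box, cls = cfg$cls, dfl = cfg$dfl, mask = cfg$mask)

  # flat per-image gradients, scattered to maps at the end
  gbox <- if (want_grads) array(0, c(reg_max * 4L, a, nimg))
  gcls <- if (want_grads) array(0, c(nc, a, nimg))
  gcoef <- if (want_grads) array(0, c(npr, a, nimg))
  gproto <- if (want_grads) array(0, dim(preds$proto))

  l_box <- l_cls <- l_dfl <- l_mask <- 0
  n_pos_total <- 0
  per_image <- vector("list", nimg)
  for (n in seq_len(nimg)) {
    fl <- flatten_preds(preds, n)
    dec <- decode_distances(fl$box, reg_max)
    asg <- assign_targets(preds, gt_list[[n]]$instances, image = n,
                          topk = cfg$topk, alpha = cfg$alpha,
                          beta = cfg$beta, anchors = anchors, fl = fl,
                          dec = dec)
    gp <- gt_pack(gt_list[[n]]$instances, preds$input_size, proto_hw)
    pos <- which(asg$assign > 0L)
    n_pos_total <- n_pos_total + length(pos)
    per_image[[n]] <- list(fl = fl, dec = dec, asg = asg, gp = gp,
                           pos = pos)
  }
  denom <- max(1, n_pos_total)

  for (n in seq_len(nimg)) {
    im <- per_image[[n]]
    fl <- im$fl; dec <- im$dec; asg <- im$asg; gp <- im$gp; pos <- im$pos
    # classification: BCE on every anchor-class; positives carry their
    # target class
    tcls <- matrix(0, nc, a)
    if (length(pos))
      tcls[cbind(gp$cls[asg$assign[pos]] + 1L, pos)] <- 1
    l_cls <- l_cls + sum(bce_logits(fl$cls, tcls))
    if (want_grads)
      gcls[, , n] <- (sigmoid(fl$cls) - tcls) * w[["cls"]] / denom

    if (length(pos)) {
      gt_of <- asg$assign[pos]
      st <- anchors$stride[pos]
      gtb <- gp$boxes[, gt_of, drop = FALSE]
      pb <- asg$pred_boxes[, pos, drop = FALSE]
      # box: 1 - CIoU
      ci <- ciou_vec(pb, gtb)
      l_box <- l_box + sum(1 - ci)
      # dfl: two-hot cross-entropy on the bracketing bins of each side
      tdist <- rbind((anchors$ax[pos] - gtb[1L, ]) / st,
                     (anchors$ay[pos] - gtb[2L, ]) / st,
                     (gtb[3L, ] - anchors$ax[pos]) / st,
                     (gtb[4L, ] - anchors$ay[pos]) / st)
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 1e-3)
      probs_pos <- dec$probs[, , pos, drop = FALSE]
      lo <- floor(tdist); hi <- lo + 1; wl <- hi - tdist; wh <- tdist - lo
      for (side in 1:4) {
        p_lo <- probs_pos[cbind(lo[side, ] + 1, side, seq_along(pos))]
        p_hi <- probs_pos[cbind(pmin(hi[side, ], reg_max - 1) + 1, side,
                                seq_along(pos))]
        l_dfl <- l_dfl + sum(-wl[side, ] * log(pmax(p_lo, 1e-12)) -
                               wh[side, ] * log(pmax(p_hi, 1e-12)))
      }
      if (want_grads) {
        # numeric CIoU gradient w.r.t. the four side distances (in stride
        # units), chained through the softmax-expectation decode
        eps <- 1e-2
        dists <- im$dec$dist[, pos, drop = FALSE]
        dgrad <- matrix(0, 4L, length(pos))
        for (side in 1:4) {
          dp <- dists; dp[side, ] <- dp[side, ] + eps
          dm <- dists; dm[side, ] <- dm[side, ] - eps
          bp <- boxes_from_dist_at(dp, anchors, pos)
          bm <- boxes_from_dist_at(dm, anchors, pos)
          dgrad[side, ] <- ((1 - ciou_vec(bp, gtb)) -
                              (1 - ciou_vec(bm, gtb))) / (2 * eps)
        }
        bins <- seq_len(reg_max) - 1
        for (k in seq_along(pos)) {
          pk <- matrix(probs_pos[, , k], reg_max, 4L)
          # d dist / d logit = p * (bins - E)
          e <- colSums(pk * bins)
          jac <- pk * (matrix(bins, reg_max, 4L) - rep(e, each = reg_max))
          gb <- jac * rep(dgrad[, k] * w[["box"]] / denom, each = reg_max)
          # dfl gradient: softmax minus two-hot
          tw <- matrix(0, reg_max, 4L)
          tw[cbind(lo[, k] + 1, 1:4)] <- wl[, k]
          hi_idx <- pmin(hi[, k], reg_max - 1) + 1
          tw[cbind(hi_idx, 1:4)] <- tw[cbind(hi_idx, 1:4)] + wh[, k]
          gb <- gb + (pk - tw) * w[["dfl"]] / denom
          gbox[, pos[k], n] <- as.vector(gb)
        }
      }
      # mask: BCE of assembled prototype mask vs gt mask inside the gt box
      pm <- matrix(preds$proto[, , , n], npr, proto_hw * proto_hw)
      cpos <- fl$coef[, pos, drop = FALSE]
      mlog <- crossprod(cpos, pm)                 # npos x Lp
      scale_p <- preds$input_size / proto_hw
      wt <- matrix(0, length(pos), proto_hw * proto_hw)
      tmask <- t(gp$masks[, gt_of, drop = FALSE])
      cy <- rep(seq_len(proto_hw) - 0.5, times = proto_hw)
      cx <- rep(seq_len(proto_hw) - 0.5, each = proto_hw)
      for (k in seq_along(pos)) {
        bb <- gtb[, k] / scale_p
        inb <- cx >= bb[1L] & cx <= bb[3L] & cy >= bb[2L] & cy <= bb[4L]
        wt[k, inb] <- 1 / max(sum(inb), 1)
      }
      l_mask <- l_mask + sum(wt * bce_logits(mlog, tmask))
      if (want_grads) {
        gm <- (sigmoid(mlog) - tmask) * wt * w[["mask"]] / denom
        gcoef[, pos, n] <- pm %*% t(gm)
        gproto[, , , n] <- gproto[, , , n] +
          array(cpos %*% gm, c(npr, proto_hw, proto_hw))
      }
    }
  }
  lb <- loss_breakdown(l_box / denom, l_cls / denom, l_dfl / denom,
                       l_mask / denom, weights = w)
  if (!want_grads) return(lb)
  # scatter flat anchor gradients back into per-scale maps
  per_scale <- anchors$per_scale
  offs <- c(0L, cumsum(per_scale))
  gs <- vector("list", 3L)
  for (i in 1:3) {
    sc <- preds$scales[[i]]
    d <- dim(sc$box)
    idx <- offs[i] + seq_len(per_scale[i])
    gs[[i]] <- list(
      box = array(gbox[, idx, , drop = FALSE], d),
      cls = array(gcls[, idx, , drop = FALSE], dim(sc$cls)),
      coef = array(gcoef[, idx, , drop = FALSE], dim(sc$coef)))
  }
  list(loss = lb, grads = list(scales = gs, proto = gproto),
       n_pos = n_pos_total)
}

boxes_from_dist_at <- function(dist, anchors, pos) {
  rbind(anchors$ax[pos] - dist[1L, ] * anchors$stride[pos],
        anchors$ay[pos] - dist[2L, ] * anchors$stride[pos],
        anchors$ax[pos] + dist[3L, ] * anchors$stride[pos],
        anchors$ay[pos] + dist[4L, ] * anchors$stride[pos])
}

#' Compute the four-component loss for given predictions and targets
#'
#' @param preds `raw_predictions`.
#' @param gt_list list (length = batch) of [image_sample()]-like objects
#'   with `$instances`.
#' @param cfg a [train_config()] providing loss weights and assigner
#'   hyperparameters.
#' @return a [loss_breakdown()].
#' @export
compute_losses <- function(preds, gt_list, cfg = train_config()) {
  detection_loss(preds, gt_list, cfg, want_grads = FALSE)
}
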