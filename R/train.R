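# Label-consistent augmentations and the SGD training loop.

# Sutherland-Hodgman clip of a normalized polygon to the unit square.
clip_polygon_unit <- function(p) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- NULL
    for (i in seq_len(n)) {
      a <- pts[if (i == 1L) n else i - 1L, ]
      b <- pts[i, ]
      ain <- inside(a); bin <- inside(b)
      if (bin) {
        if (!ain) out <- rbind(out, intersect(a, b))
        out <- rbind(out, b)
      } else if (ain) {
        out <- rbind(out, intersect(a, b))
      }
    }
    if (is.null(out)) matrix(0, 0L, 2L) else out
  }
  lerp <- function(a, b, t) a + t * (b - a)
  p <- clip_edge(p, function(q) q[1L] >= 0, function(a, b)
    lerp(a, b, (0 - a[1L]) / (b[1L] - a[1L])))
  p <- clip_edge(p, function(q) q[1L] <= 1, function(a, b)
    lerp(a, b, (1 - a[1L]) / (b[1L] - a[1L])))
  p <- clip_edge(p, function(q) q[2L] >= 0, function(a, b)
    lerp(a, b, (0 - a[2L]) / (b[2L] - a[2L])))
  p <- clip_edge(p, function(q) q[2L] <= 1, function(a, b)
    lerp(a, b, (1 - a[2L]) / (b[2L] - a[2L])))
  p
}

remap_instances <- function(instances, fx) {
  out <- list()
  for (inst in instances) {
    p <- fx(inst$polygon)
    p <- clip_polygon_unit(p)
    if (nrow(p) >= 3L && abs(polygon_area(p)) > 1e-8)
      out <- c(out, list(instance_annotation(inst$class_id,
                                             pmin(pmax(p, 0), 1))))
  }
  out
}

#' Deterministic sample transforms
#'
#' `flip_sample()` mirrors raster and polygons; applying the same flip twice
#' is the identity. `shift_sample()` translates by whole pixels with gray
#' border fill, clipping polygons at the border and dropping degenerate
#' remainders. `mosaic_sample()` stitches four samples into one canvas
#' split at a random interior point, rescaling each tile's polygons.
#' `cutout_sample()` blanks random coarse patches (labels untouched).
#'
#' @param sample an [image_sample()].
#' @param horizontal flip axis.
#' @return transformed [image_sample()].
#' @export
flip_sample <- function(sample, horizontal = TRUE) {
  img <- sample$image
  if (horizontal) {
    img <- img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
    fx <- function(p) cbind(1 - p[, 1L], p[, 2L])
  } else {
    img <- img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
    fx <- function(p) cbind(p[, 1L], 1 - p[, 2L])
  }
  image_sample(img, remap_instances(sample$instances, fx),
               sample$source_id)
}

#' @rdname flip_sample
#' @param dx,dy shift in pixels (positive = right/down).
#' @export
shift_sample <- function(sample, dx, dy) {
  d <- dim(sample$image)
  h <- d[1L]; w <- d[2L]
  img <- array(0.5, d)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  yok <- ys >= 1L & ys <= h; xok <- xs >= 1L & xs <= w
  img[which(yok), which(xok), ] <-
    sample$image[ys[yok], xs[xok], , drop = FALSE]
  fx <- function(p) cbind(p[, 1L] + dx / w, p[, 2L] + dy / h)
  image_sample(img, remap_instances(sample$instances, fx),
               sample$source_id)
}

#' @rdname flip_sample
#' @param samples list of exactly 4 samples of equal size.
#' @param split_xy optional split point as fractions in (0, 1)^2; random in
#'   `[0.3, 0.7]` when missing.
#' @export
mosaic_sample <- function(samples, split_xy = NULL) {
  stopifnot(length(samples) == 4L)
  d <- dim(samples[[1L]]$image)
  s <- d[1L]
  if (is.null(split_xy)) split_xy <- runif(2L, 0.3, 0.7)
  sx <- round(split_xy[1L] * s); sy <- round(split_xy[2L] * s)
  tiles <- list(c(1L, sy, 1L, sx), c(1L, sy, sx + 1L, s),
                c(sy + 1L, s, 1L, sx), c(sy + 1L, s, sx + 1L, s))
  img <- array(0, d)
  insts <- list()
  for (i in 1:4) {
    t <- tiles[[i]]
    th <- t[2L] - t[1L] + 1L; tw <- t[4L] - t[3L] + 1L
    chw <- aperm(samples[[i]]$image, c(3L, 1L, 2L))
    img[t[1L]:t[2L], t[3L]:t[4L], ] <-
      aperm(bilinear_resize(chw, th, tw), c(2L, 3L, 1L))
    ox <- (t[3L] - 1L) / s; oy <- (t[1L] - 1L) / s
    fx <- function(p) cbind(p[, 1L] * tw / s + ox, p[, 2L] * th / s + oy)
    insts <- c(insts, remap_instances(samples[[i]]$instances, fx))
  }
  image_sample(img, insts, samples[[1L]]$source_id)
}

#' @rdname flip_sample
#' @param rate expected fraction of blanked area per patch draw.
#' @export
cutout_sample <- function(sample, rate = 0.1) {
  d <- dim(sample$image)
  img <- sample$image
  for (k in seq_len(sample.int(3L, 1L))) {
    ph <- max(2L, round(runif(1L, 0.5, 1.5) * sqrt(rate) * d[1L]))
    pw <- max(2L, round(runif(1L, 0.5, 1.5) * sqrt(rate) * d[2L]))
    y0 <- sample.int(max(d[1L] - ph, 1L), 1L)
    x0 <- sample.int(max(d[2L] - pw, 1L), 1L)
    img[y0:(y0 + ph - 1L), x0:(x0 + pw - 1L), ] <- 0.5
  }
  image_sample(img, sample$instances, sample$source_id)
}

#' Apply the configured augmentation pipeline to one sample
#'
#' Mosaic (when enabled and a pool is supplied) stitches the sample with
#' three random pool picks; horizontal/vertical flips and whole-pixel
#' shifts are applied with probability 0.5 each where enabled; coarse
#' cutout runs at `dropout_rate`. Uses the current RNG stream.
#'
#' @param sample an [image_sample()].
#' @param cfg a [train_config()].
#' @param pool list of samples mosaic may draw from.
#' @param use_mosaic override to disable mosaic (e.g. late in training).
#' @return augmented [image_sample()].
#' @export
augment <- function(sample, cfg = train_config(), pool = list(),
                    use_mosaic = cfg$mosaic) {
  if (use_mosaic && length(pool) >= 3L && runif(1L) < 0.5) {
    others <- pool[sample.int(length(pool), 3L)]
    sample <- mosaic_sample(c(list(sample), others))
  }
  if (cfg$fliplr && runif(1L) < 0.5) sample <- flip_sample(sample, TRUE)
  if (cfg$flipud && runif(1L) < 0.5) sample <- flip_sample(sample, FALSE)
  if (cfg$pixel_shift && runif(1L) < 0.5) {
    d <- dim(sample$image)
    sample <- shift_sample(sample, sample.int(21L, 1L) - 11L,
                           sample.int(21L, 1L) - 11L)
  }
  if (cfg$dropout_rate > 0 && runif(1L) < 0.5)
    sample <- cutout_sample(sample, cfg$dropout_rate)
  sample
}

samples_to_batch <- function(samples) {
  s <- dim(samples[[1L]]$image)[1L]
  x <- array(0, c(3L, s, s, length(samples)))
  for (i in seq_along(samples))
    x[, , , i] <- aperm(samples[[i]]$image, c(3L, 1L, 2L))
  x
}

sgd_init <- function(leaves) {
  for (lf in leaves)
    lf$mom <- lapply(lf$par, function(p) numeric(length(p)))
  invisible(NULL)
}

sgd_step <- function(leaves, lr, momentum, weight_decay) {
  for (lf in leaves) {
    decay_w <- lf$type %in% c("conv2d", "dwconv", "changate")
    for (nm in names(lf$par)) {
      g <- lf$gr[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0 && decay_w && substr(nm, 1L, 1L) == "w")
        g <- g + weight_decay * as.vector(lf$par[[nm]])
      v <- momentum * lf$mom[[nm]] + g
      lf$mom[[nm]] <- v
      lf$par[[nm]] <- lf$par[[nm]] - lr * v
    }
  }
  invisible(NULL)
}

lr_at <- function(cfg, epoch, step, steps_per_epoch) {
  frac <- (epoch - 1 + (step - 1) / max(steps_per_epoch, 1)) /
    max(cfg$warmup_epochs, 1e-9)
  if (epoch <= cfg$warmup_epochs && frac < 1)
    return(cfg$lr0 * max(frac, 0.05))
  t <- (epoch - 1) / max(cfg$epochs - 1, 1)
  cfg$lr0 * (cfg$lrf + (1 - cfg$lrf) * 0.5 * (1 + cos(pi * t)))
}

#' Train the segmentation model
#'
#' Seeded SGD with momentum, weight decay, linear warmup and cosine decay;
#' early stopping on validation loss; the best-on-validation parameter
#' state is restored into the returned model. Augmentation settings apply
#' uniformly across epochs, so per-epoch training losses are measured on a
#' stationary data distribution.
#'
#' @param model a [build_model()] result (trained in place).
#' @param train_set,val_set lists of [image_sample()] at the model's input
#'   size.
#' @param cfg a [train_config()].
#' @param eval_map whether to compute validation box mAP@50 curves.
#' @param map_every epoch interval for the mAP evaluation (it adds one
#'   inference + evaluation pass; the final epoch is always evaluated).
#' @param verbose print one line per epoch.
#' @return list with `$model`, `$curves` (per-epoch data.frame: losses,
#'   val loss, val mAP@50), `$best_epoch`, `$epochs_run`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        eval_map = TRUE, map_every = 5L, verbose = FALSE) {
  stopifnot(length(train_set) >= 1L)
  set.seed(cfg$seed)
  leaves <- model_leaves(model)
  sgd_init(leaves)
  n <- length(train_set)
  steps <- ceiling(n / cfg$batch_size)
  best_val <- Inf; best_state <- NULL; best_epoch <- 0L; bad <- 0L
  curves <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    ep_loss <- c(box = 0, cls = 0, dfl = 0, mask = 0, total = 0)
    for (s in seq_len(steps)) {
      take <- idx[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
      batch <- lapply(train_set[take], augment, cfg = cfg,
                      pool = train_set)
      x <- samples_to_batch(batch)
      preds <- model_forward(model, x, training = TRUE)
      for (lf in leaves) lf$gr <- list()
      dl <- detection_loss(preds, batch, cfg, want_grads = TRUE)
      if (!is.finite(dl$loss$total))
        stop("training diverged at epoch ", epoch, " step ", s,
             " (non-finite loss)")
      model_backward(model, dl$grads)
      sgd_step(leaves, lr_at(cfg, epoch, s, steps), cfg$momentum,
               cfg$weight_decay)
      ep_loss <- ep_loss + c(dl$loss$box, dl$loss$cls, dl$loss$dfl,
                             dl$loss$mask, dl$loss$total)
    }
    ep_loss <- ep_loss / steps
    want_map <- eval_map &&
      (epoch %% map_every == 0L || epoch == cfg$epochs)
    val <- validation_metrics(model, val_set, cfg, want_map)
    curves <- rbind(curves, data.frame(
      epoch = epoch, box = ep_loss[1L], cls = ep_loss[2L],
      dfl = ep_loss[3L], mask = ep_loss[4L], total = ep_loss[5L],
      val_total = val$loss, val_map50 = val$map50))
    if (verbose)
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  val mAP@50 %.3f",
        epoch, ep_loss[5L], val$loss, val$map50))
    if (is.finite(val$loss) && val$loss < best_val - 1e-6) {
      best_val <- val$loss
      best_state <- model_state(model)
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > cfg$patience) break
    }
  }
  if (!is.null(best_state)) model_load_state(model, best_state)
  rownames(curves) <- NULL
  list(model = model, curves = curves, best_epoch = best_epoch,
       epochs_run = nrow(curves))
}

validation_metrics <- function(model, val_set, cfg, eval_map = TRUE) {
  if (!length(val_set)) return(list(loss = NA_real_, map50 = NA_real_))
  total <- 0; nb <- 0L
  bs <- cfg$batch_size
  for (s in seq_len(ceiling(length(val_set) / bs))) {
    take <- ((s - 1L) * bs + 1L):min(s * bs, length(val_set))
    x <- samples_to_batch(val_set[take])
    preds <- model_forward(model, x, training = FALSE)
    lb <- tryCatch(
      detection_loss(preds, val_set[take], cfg, want_grads = FALSE)$total,
      error = function(e) Inf)
    total <- total + lb
    nb <- nb + 1L
  }
  map50 <- NA_real_
  if (eval_map) {
    dets <- lapply(val_set, function(s)
      segment_image(model, s$image, with_masks = FALSE))
    rep50 <- evaluate_detections(dets, val_set, modes = "box")
    map50 <- rep50$box$ap50[rep50$box$class == "all"]
  }
  list(loss = total / nb, map50 = map50)
}
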