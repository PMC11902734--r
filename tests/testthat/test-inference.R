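# Decoding, NMS, mask assembly, end-to-end segmentation pipeline.

test_that("decode: distribution expectation and thresholding", {
  # one-hot bin b -> side distance exactly b * stride
  p <- local({
    q <- list(scales = list(), strides = 8L, input_size = 64L, n = 1L)
    q$scales[[1]] <- list(box = array(-30, c(64, 8, 8, 1)),
                          cls = array(-30, c(2, 8, 8, 1)),
                          coef = array(0, c(4, 8, 8, 1)))
    q$proto <- array(0, c(4, 8, 8, 1))
    class(q) <- "raw_predictions"
    q
  })
  b <- 3L
  for (side in 0:3) p$scales[[1]]$box[side * 16L + b + 1L, 2, 2, 1] <- 30
  p$scales[[1]]$cls[1, 2, 2, 1] <- 5
  cands <- decode_predictions(p, conf_threshold = 0.5)
  expect_equal(ncol(cands$boxes), 1L)
  # anchor (h=2, w=2) center is (12, 12); all sides distance 3*8 = 24
  expect_equal(as.vector(cands$boxes),
               c(12 - 24, 12 - 24, 12 + 24, 12 + 24), tolerance = 1e-4)
  expect_equal(cands$classes, 0L)
  # all logits very negative -> nothing above threshold
  p$scales[[1]]$cls[] <- -30
  expect_equal(length(decode_predictions(p, 0.25)$scores), 0L)
})

test_that("decoded distances match a direct softmax-expectation oracle", {
  set.seed(61)
  box <- matrix(rnorm(64 * 5), 64, 5)
  dec <- orchardseg:::decode_distances(box, 16L)
  for (a in 1:5) for (side in 1:4) {
    lg <- box[(side - 1) * 16 + 1:16, a]
    pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
    expect_equal(dec$dist[side, a], sum(pr * 0:15), tolerance = 1e-10)
  }
})

test_that("box encoded to one-hot bins decodes to itself within half a pixel", {
  # round-trip: choose integer distances, encode one-hot, decode
  set.seed(62)
  for (rep in 1:10) {
    d <- sample(0:15, 4, replace = TRUE)
    lg <- matrix(-30, 64, 1)
    for (side in 1:4) lg[(side - 1) * 16 + d[side] + 1, 1] <- 30
    dec <- orchardseg:::decode_distances(lg, 16L)
    expect_lt(max(abs(dec$dist[, 1] - d)) * 8, 0.5)
  }
})

test_that("NMS matches the quadratic reference and breaks ties by index", {
  # two identical boxes
  boxes <- cbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  keep <- nms(boxes, c(0.9, 0.8), c(0L, 0L), 0.7)
  expect_identical(keep, 1L)
  # disjoint boxes all survive
  boxes2 <- cbind(c(0, 0, 5, 5), c(10, 10, 15, 15), c(20, 20, 25, 25))
  expect_length(nms(boxes2, c(.5, .9, .7), c(0L, 0L, 0L), 0.5), 3L)
  # different classes never suppress each other
  keep3 <- nms(boxes, c(0.9, 0.8), c(0L, 1L), 0.5)
  expect_length(keep3, 2L)

  # 200 random boxes vs an exhaustive reference
  set.seed(63)
  n <- 200
  x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
  bx <- rbind(x1, y1, x1 + runif(n, 5, 30), y1 + runif(n, 5, 30))
  sc <- runif(n)
  cl <- sample(0:1, n, replace = TRUE)
  got <- nms(bx, sc, cl, 0.5)
  # independent O(n^2) reference
  ref_iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ord <- order(-sc, seq_len(n))
  supp <- rep(FALSE, n)
  want <- integer(0)
  for (a in seq_len(n)) {
    i <- ord[a]
    if (supp[i]) next
    want <- c(want, i)
    for (b in seq_len(n)[-seq_len(a)]) {
      j <- ord[b]
      if (!supp[j] && cl[j] == cl[i] && ref_iou(bx[, i], bx[, j]) > 0.5)
        supp[j] <- TRUE
    }
  }
  expect_identical(sort(got), sort(want))
  # survivor order is by descending score
  expect_true(all(diff(sc[got]) <= 0))
})

test_that("mask assembly: thresholding convention and crop", {
  proto <- array(0, c(3, 8, 8))
  # all-zero coefficients: sigmoid(0) = 0.5 everywhere; >= 0.5 is
  # foreground, so the full box is filled
  m <- assemble_mask(c(0, 0, 0), proto, box = c(8, 8, 24, 24),
                     out_size = 32)
  expect_true(all(m[9:24, 9:24]))
  expect_false(any(m[1:8, ]))
  expect_false(any(m[, 25:32]))
  # a single strongly positive prototype region restricted by the box
  proto[1, 1:4, 1:4] <- 20
  proto[1, 5:8, ] <- -20
  proto[1, , 5:8] <- -20
  m2 <- assemble_mask(c(1, 0, 0), proto, box = c(0, 0, 32, 32),
                      out_size = 32)
  expect_true(m2[4, 4])
  expect_false(m2[28, 28])
  # random case equals the naive per-pixel combination oracle
  set.seed(64)
  proto3 <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  co <- rnorm(3)
  m3 <- assemble_mask(co, proto3, box = c(0, 0, 16, 16), out_size = 16)
  logit <- apply(proto3 * co, c(2, 3), sum)
  prob <- 1 / (1 + exp(-logit))
  up <- bilinear_resize(array(prob, c(1, 8, 8)), 16, 16)
  expect_identical(m3, matrix(up[1, , ] >= 0.5, 16, 16))
})

test_that("segment_image runs the full pipeline deterministically", {
  set.seed(65)
  model <- build_model(model_spec(preset = "tiny", input_size = 96L))
  s <- generate_scene(scene_config(image_size = 120), 9)
  d1 <- segment_image(model, s$image, conf = 0.25, iou = 0.7)
  d2 <- segment_image(model, s$image, conf = 0.25, iou = 0.7)
  expect_identical(d1, d2)
  for (dt in d1) {
    expect_true(dt$class_id %in% c(0L, 1L))
    expect_gte(dt$score, 0.25)
    expect_lt(dt$box[1], dt$box[3])
    expect_lt(dt$box[2], dt$box[4])
    expect_equal(dim(dt$mask), dim(s$image)[1:2])
    # mask confined to the box (with the integer-crop margin)
    ys <- range(which(rowSums(dt$mask) > 0))
    if (any(dt$mask))
      expect_gte(ys[1], floor(dt$box[2]))
  }
})

test_that("COCO-results round trip preserves boxes, scores and masks", {
  set.seed(66)
  dets <- list(list(
    list(class_id = 0L, score = 0.9, box = c(2, 3, 20, 30),
         mask = matrix(runif(40 * 40) > 0.6, 40, 40)),
    list(class_id = 1L, score = 0.4, box = c(5, 5, 12, 9),
         mask = matrix(FALSE, 40, 40))),
    list())
  path <- tempfile(fileext = ".json")
  write_coco_results(dets, path)
  back <- read_coco_results(path, n_images = 2)
  expect_length(back, 2)
  expect_length(back[[2]], 0)
  expect_equal(back[[1]][[1]]$box, dets[[1]][[1]]$box)
  expect_equal(back[[1]][[1]]$score, 0.9)
  expect_identical(back[[1]][[1]]$mask, dets[[1]][[1]]$mask)
  expect_identical(back[[1]][[2]]$mask, dets[[1]][[2]]$mask)
})
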