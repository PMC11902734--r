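# Metric suite: IoU, greedy matching, interpolated AP, full reports.

det <- function(class_id, score, box, mask = NULL)
  list(class_id = as.integer(class_id), score = score, box = box,
       mask = mask)

test_that("IoU analytic cases for boxes and masks", {
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  # two unit squares overlapping by half -> 0.5 / 1.5 = 1/3
  expect_equal(iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)), 1 / 3)
  expect_equal(iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)),
               iou(c(0.5, 0, 1.5, 1), c(0, 0, 1, 1)))
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1:2, 1:4] <- TRUE
  expect_equal(iou(a, b), 4 / 8)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, matrix(FALSE, 4, 4)), 0)
})

test_that("greedy matching: perfect, duplicate, and oracle behaviour", {
  gts <- list(det(0L, 1, c(0, 0, 10, 10)), det(0L, 1, c(20, 20, 30, 30)))
  perfect <- list(det(0L, .9, c(0, 0, 10, 10)),
                  det(0L, .8, c(20, 20, 30, 30)))
  m <- match_detections(perfect, gts, 0.5, "box")
  expect_true(all(m$tp))
  dup <- list(det(0L, .9, c(0, 0, 10, 10)), det(0L, .8, c(0, 0, 10, 10)))
  m2 <- match_detections(dup, gts, 0.5, "box")
  expect_identical(m2$tp, c(TRUE, FALSE))
  # class mismatch never matches
  wrong <- list(det(1L, .9, c(0, 0, 10, 10)))
  expect_false(any(match_detections(wrong, gts, 0.5, "box")$tp))
})

test_that("interpolated AP on hand-computed cases", {
  # all TP covering all gts
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  # no predictions but targets exist
  expect_equal(average_precision(logical(0), 3), 0)
  # (TP, FP, TP) with 2 gts: precision envelope 1 up to recall .5,
  # then 2/3 -> (51 * 1 + 50 * 2/3) / 101
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               (51 + 50 * 2 / 3) / 101)
  # FP-only
  expect_equal(average_precision(c(FALSE, FALSE), 2), 0)
  # AP is monotone non-increasing in the IoU threshold
  set.seed(71)
  gt <- generate_scene(scene_config(image_size = 96), 11)
  dets <- lapply(gt$instances, function(inst) {
    b <- inst$bbox * 96
    jit <- runif(4, -3, 3)
    det(inst$class_id, runif(1, .5, 1), b + jit)
  })
  aps <- vapply(seq(0.5, 0.95, 0.05), function(thr) {
    m <- match_detections(dets, orchardseg:::gt_objects(gt, FALSE),
                          thr, "box")
    average_precision(m$tp, length(gt$instances))
  }, 0)
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("adding a lowest-score false positive never raises AP", {
  set.seed(72)
  for (rep in 1:20) {
    tp <- runif(8) > 0.4
    n_gt <- sum(tp) + sample(0:2, 1)
    base <- average_precision(tp, n_gt)
    worse <- average_precision(c(tp, FALSE), n_gt)
    expect_lte(worse, base + 1e-12)
  }
})

test_that("mAP@50-95 threshold counting", {
  # one prediction with IoU exactly 0.6 against its gt:
  # AP = 1 at thresholds {0.5, 0.55, 0.6}, 0 above -> mean 0.3
  gt_box <- c(0, 0, 10, 10)
  pred_box <- c(0, 4, 10, 14)   # IoU = 6/14... construct exactly 0.6:
  # boxes (0,0,10,10) vs (0,2.5,10,12.5): inter 75, union 125 -> 0.6
  pred_box <- c(0, 2.5, 10, 12.5)
  gts1 <- list(list(list(class_id = 0L, box = gt_box, mask = NULL)))
  dets1 <- list(list(det(0L, .9, pred_box)))
  got <- map_50_95(dets1, gts1, mode = "box", classes = 0L)
  expect_equal(got, 0.3)
})

test_that("self-evaluation of ground truth scores perfectly", {
  set.seed(73)
  scenes <- generate_scenes(3, scene_config(image_size = 96), seed = 100)
  dets <- lapply(scenes, function(s) {
    d <- dim(s$image)
    lapply(s$instances, function(inst)
      det(inst$class_id, 1.0, inst$bbox * c(d[2], d[1], d[2], d[1]),
          polygon_to_mask(inst$polygon, d[1], d[2]) != 0L))
  })
  rep <- evaluate_detections(dets, scenes, modes = c("box", "mask"))
  for (mode in c("box", "mask")) {
    df <- rep[[mode]]
    expect_equal(df$precision, rep(1, nrow(df)))
    expect_equal(df$recall, rep(1, nrow(df)))
    expect_equal(df$ap50, rep(1, nrow(df)))
    expect_equal(df$ap50_95, rep(1, nrow(df)))
  }
})

test_that("empty predictions give zero precision and recall", {
  scenes <- generate_scenes(2, scene_config(image_size = 96), seed = 200)
  rep <- evaluate_detections(rep(list(list()), 2), scenes, modes = "box")
  expect_equal(rep$box$precision, rep(0, 3))
  expect_equal(rep$box$recall, rep(0, 3))
  expect_equal(rep$box$ap50, rep(0, 3))
})

test_that("box and mask modes agree when masks are filled boxes", {
  # integer-aligned boxes: the pixelized filled-box mask has exactly the
  # box's area, so box IoU and mask IoU coincide and the reports match
  set.seed(74)
  d <- c(64L, 64L)
  box_mask <- function(b) {
    m <- matrix(FALSE, d[1], d[2])
    m[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
    m
  }
  gt_boxes <- list(c(4L, 4L, 30L, 28L), c(34L, 30L, 60L, 58L),
                   c(10L, 40L, 16L, 60L))
  cls <- c(0L, 0L, 1L)
  insts <- lapply(seq_along(gt_boxes), function(i) {
    b <- gt_boxes[[i]] / 64
    instance_annotation(cls[i], matrix(c(b[1], b[3], b[3], b[1],
                                         b[2], b[2], b[4], b[4]), 4, 2))
  })
  gt <- list(image_sample(array(0.5, c(64, 64, 3)), insts))
  dets <- list(lapply(seq_along(gt_boxes), function(i) {
    b <- gt_boxes[[i]] + sample(-2:2, 4, replace = TRUE)
    b <- pmin(pmax(b, 0L), 64L)
    det(cls[i], runif(1, .5, 1), b, box_mask(b))
  }))
  rep <- evaluate_detections(dets, gt, modes = c("box", "mask"))
  expect_equal(rep$box$ap50, rep$mask$ap50, tolerance = 1e-12)
  expect_equal(rep$box$ap50_95, rep$mask$ap50_95, tolerance = 1e-12)
})

test_that("golden fixture: six predictions against four ground truths", {
  # Hand-computed report. Image 100 x 100. GTs: two apples A1 (0,0,20,20),
  # A2 (50,50,80,80); two stems S1 (30,0,34,10), S2 (60,10,64,22).
  gt <- list(list(
    list(class_id = 0L, box = c(0, 0, 20, 20)),
    list(class_id = 0L, box = c(50, 50, 80, 80)),
    list(class_id = 1L, box = c(30, 0, 34, 10)),
    list(class_id = 1L, box = c(60, 10, 64, 22))))
  dets <- list(list(
    det(0L, 0.95, c(0, 0, 20, 20)),      # TP (A1, IoU 1)
    det(0L, 0.90, c(1, 1, 21, 21)),      # FP (A1 already matched)
    det(0L, 0.60, c(50, 50, 80, 80)),    # TP (A2)
    det(1L, 0.80, c(30, 0, 34, 10)),     # TP (S1)
    det(1L, 0.40, c(90, 90, 95, 99)),    # FP (no stem there)
    det(0L, 0.30, c(40, 40, 45, 45))))   # FP apple
  # apple flags by descending score: (T, F, T, F) over 2 gts
  #   -> AP = (51 + 50 * 2/3) / 101
  # stem flags: (T, F) over 2 gts -> precision envelope: 1 to recall 0.5,
  #   0 beyond -> AP = 51/101
  ap_apple <- (51 + 50 * 2 / 3) / 101
  ap_stem <- 51 / 101
  # wrap as one image; gt via image_sample with box polygons
  insts <- lapply(gt[[1]], function(g) {
    b <- g$box / 100
    instance_annotation(g$class_id,
                        matrix(c(b[1], b[3], b[3], b[1],
                                 b[2], b[2], b[4], b[4]), 4, 2))
  })
  gts <- list(image_sample(array(0.5, c(100, 100, 3)), insts))
  rep <- evaluate_detections(dets, gts, modes = "box")
  df <- rep$box
  expect_equal(df$ap50[df$class == "apple"], ap_apple, tolerance = 1e-12)
  expect_equal(df$ap50[df$class == "stem"], ap_stem, tolerance = 1e-12)
  expect_equal(df$ap50[df$class == "all"], (ap_apple + ap_stem) / 2)
  # max-F1 operating points, by hand:
  # apple: cum (P, R) = (1, .5), (.5, .5), (2/3, 1), (.5, 1);
  #   F1 = .667, .5, .8, .667 -> max at cutoff 3: P = 2/3, R = 1
  expect_equal(df$precision[df$class == "apple"], 2 / 3)
  expect_equal(df$recall[df$class == "apple"], 1)
  # stem: (1, .5) F1 = 2/3; (.5, .5) F1 = .5 -> P = 1, R = .5
  expect_equal(df$precision[df$class == "stem"], 1)
  expect_equal(df$recall[df$class == "stem"], 0.5)
})
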