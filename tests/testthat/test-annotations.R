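# Data model, label I/O, rasterization, preprocessing, dataset splitting.

write_tmp_png <- function(img) {
  path <- tempfile(fileext = ".png")
  png::writePNG(img, path)
  path
}

test_that("YOLO-seg labels parse, derive boxes, and reject malformed lines", {
  img <- write_tmp_png(array(0.5, c(8, 10, 3)))
  lbl <- tempfile(fileext = ".txt")

  writeLines("0 0.1 0.1 0.9 0.1 0.5 0.9", lbl)
  s <- read_yolo_seg(lbl, img)
  expect_length(s$instances, 1)
  expect_identical(s$instances[[1]]$class_id, 0L)
  expect_equal(s$instances[[1]]$bbox, c(0.1, 0.1, 0.9, 0.9))

  writeLines(character(0), lbl)
  expect_length(read_yolo_seg(lbl, img)$instances, 0)

  writeLines("1 0.2 0.2 0.3", lbl)
  expect_error(read_yolo_seg(lbl, img), "line 1")
  writeLines("2 0.1 0.1 0.9 0.1 0.5 0.9", lbl)
  expect_error(read_yolo_seg(lbl, img), "class")
  writeLines(c("0 0.1 0.1 0.9 0.1 0.5 0.9", "0 0.1 0.1 1.9 0.1 0.5 0.9"),
             lbl)
  expect_error(read_yolo_seg(lbl, img), "line 2")
})

test_that("label write/read round-trips bit-exactly at 6 decimals", {
  set.seed(21)
  poly1 <- matrix(round(runif(8), 6), 4, 2)
  poly2 <- matrix(round(runif(10), 6), 5, 2)
  s <- image_sample(array(0.2, c(6, 6, 3)),
                    list(instance_annotation(0L, poly1),
                         instance_annotation(1L, poly2)))
  lbl <- tempfile(fileext = ".txt")
  write_yolo_seg(s, lbl)
  first <- readLines(lbl)
  img <- write_tmp_png(s$image)
  s2 <- read_yolo_seg(lbl, img)
  write_yolo_seg(s2, lbl)
  expect_identical(readLines(lbl), first)
  expect_equal(s2$instances[[1]]$polygon, poly1)
  expect_equal(s2$instances[[2]]$polygon, poly2)
})

test_that("instance invariants are enforced", {
  expect_error(instance_annotation(0L, matrix(c(0, 0, 1, 1), 2, 2)),
               "n >= 3")
  expect_error(instance_annotation(0L,
    matrix(c(0, .5, 1, 0, .5, 1) * 1.5, 3, 2)), "0, 1|\\[0, 1\\]")
  expect_error(instance_annotation(5L,
    matrix(c(0, .5, 1, 0, 1, 0), 3, 2)), "class")
  # zero-area polygon
  expect_error(instance_annotation(0L,
    matrix(c(.1, .5, .9, .2, .2, .2), 3, 2)), "area")
})

test_that("polygon rasterization follows even-odd pixel-center fill", {
  full <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(sum(polygon_to_mask(full, 4, 4)), 16)

  half <- matrix(c(0, 0.5, 0.5, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(sum(polygon_to_mask(half, 10, 10)), 50)

  expect_warning(m0 <- polygon_to_mask(
    matrix(c(.1, .1, .1, .1, .5, .9), 3, 2), 6, 6), "degenerate")
  expect_equal(sum(m0), 0)

  # random polygons against the brute-force point-in-polygon oracle
  pip <- function(px, py, qx, qy) {
    n <- length(px); inside <- FALSE; j <- n
    for (i in 1:n) {
      if ((py[i] > qy) != (py[j] > qy)) {
        xi <- px[i] + (qy - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
        if (qx < xi) inside <- !inside
      }
      j <- i
    }
    inside
  }
  set.seed(22)
  for (t in 1:20) {
    nv <- sample(3:9, 1)
    poly <- cbind(runif(nv), runif(nv))
    h <- sample(5:16, 1); w <- sample(5:16, 1)
    got <- polygon_to_mask(poly, h, w)
    for (yy in 1:h) for (xx in 1:w) {
      want <- pip(poly[, 1] * w, poly[, 2] * h, xx - 0.5, yy - 0.5)
      expect_identical(got[yy, xx] == 1L, want)
    }
  }
})

test_that("square resize: shape, identity, mean preservation", {
  set.seed(23)
  img <- array(runif(720 * 1280 * 3), c(720, 1280, 3))
  s <- image_sample(img, list(instance_annotation(0L,
    matrix(c(.2, .5, .8, .2, .8, .2), 3, 2))))
  r <- resize_to_square(s, 640)
  expect_equal(dim(r$image), c(640L, 640L, 3L))
  expect_length(r$instances, 1)
  expect_equal(r$instances[[1]]$polygon, s$instances[[1]]$polygon)

  sq <- image_sample(array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(resize_to_square(sq, 64)$image, sq$image, tolerance = 1e-12)

  # 2x2 checkerboard -> 4x4 preserves mean intensity (half-pixel bilinear)
  cb <- array(0, c(2, 2, 3))
  cb[1, 1, ] <- 1; cb[2, 2, ] <- 1
  up <- resize_to_square(image_sample(cb), 4)$image
  expect_equal(mean(up), mean(cb), tolerance = 1 / 255)

  # letterbox keeps aspect and remaps polygons into the padded frame
  lb <- resize_to_square(s, 640, letterbox = TRUE)
  expect_equal(dim(lb$image), c(640L, 640L, 3L))
  expect_true(all(lb$instances[[1]]$polygon >= 0 &
                    lb$instances[[1]]$polygon <= 1))
})

test_that("dataset split sizes reproduce the exact 70/20/10 arithmetic", {
  sp280 <- split_dataset(seq_len(280), split_fractions(), seed = 3)
  expect_equal(lengths(sp280[c("train", "test", "validation")]),
               c(train = 196L, test = 56L, validation = 28L))
  sp260 <- split_dataset(seq_len(260), split_fractions(), seed = 3)
  expect_equal(lengths(sp260[c("train", "test", "validation")]),
               c(train = 182L, test = 52L, validation = 26L))
  sp10 <- split_dataset(seq_len(10), split_fractions(), seed = 3)
  expect_equal(lengths(sp10[c("train", "test", "validation")]),
               c(train = 7L, test = 2L, validation = 1L))
})

test_that("dataset split is a seeded partition, size-stable and stratifiable", {
  x <- seq_len(97)
  sp <- split_dataset(x, split_fractions(), seed = 42)
  all_items <- c(sp$train, sp$test, sp$validation)
  expect_setequal(all_items, x)
  expect_equal(length(all_items), 97)         # disjoint + exhaustive
  sp2 <- split_dataset(x, split_fractions(), seed = 42)
  expect_identical(sp, sp2)                   # deterministic in the seed
  sp3 <- split_dataset(x, split_fractions(), seed = 43)
  expect_false(identical(sp$train, sp3$train))
  # permuting the input changes membership but never the sizes
  perm <- split_dataset(sample(x), split_fractions(), seed = 42)
  expect_equal(lengths(perm[1:3]), lengths(sp[1:3]))
  # empty input
  sp0 <- split_dataset(integer(0))
  expect_equal(lengths(sp0[1:3]),
               c(train = 0L, test = 0L, validation = 0L))
  # stratified mode partitions within each group
  grp <- rep(c("a", "b"), c(50, 47))
  sps <- split_dataset(x, split_fractions(), seed = 1, stratify_by = grp)
  expect_setequal(c(sps$train, sps$test, sps$validation), x)
  expect_equal(sum(sps$train <= 50), 35)      # round(50 * 0.7)
})

test_that("fractions are validated", {
  expect_error(split_fractions(0.7, 0.2, 0.2), "sum")
  expect_error(split_fractions(-0.1, 0.9, 0.2), "non-negative")
})

test_that("COCO JSON export/import round-trips instances", {
  set.seed(24)
  s <- generate_scene(scene_config(image_size = 96), 5)
  path <- tempfile(fileext = ".json")
  write_coco_json(list(s), path)
  back <- read_coco_json(path)
  expect_length(back, 1)
  expect_length(back[[1]]$instances, length(s$instances))
  for (i in seq_along(s$instances)) {
    expect_identical(back[[1]]$instances[[i]]$class_id,
                     s$instances[[i]]$class_id)
    expect_equal(back[[1]]$instances[[i]]$polygon,
                 s$instances[[i]]$polygon, tolerance = 1e-9)
  }
})
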