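# Data model and I/O for images with per-instance polygon annotations.
#
# Conventions: 0-based pixel coordinates, pixel centers at (x + 0.5,
# y + 0.5), boxes half-open [x_min, x_max); polygons stored normalized to
# [0, 1] relative to image width/height in the YOLO-segmentation dialect.

CLASS_NAMES <- c("apple", "stem")

#' One labeled object instance
#'
#' @param class_id integer category: 0 = apple (fruit), 1 = stem.
#' @param polygon n x 2 matrix of (x, y) vertices, normalized to `[0, 1]`,
#'   at least 3 vertices, positive area.
#' @return an `instance_annotation` with the derived tight bounding box
#'   `$bbox` = (x_min, y_min, x_max, y_max), normalized.
#' @export
instance_annotation <- function(class_id, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be an n x 2 matrix with n >= 3")
  if (any(polygon < 0 | polygon > 1))
    stop("polygon coordinates must lie in [0, 1]")
  if (!class_id %in% c(0L, 1L))
    stop("unknown class id: ", class_id)
  if (abs(polygon_area(polygon)) < 1e-12)
    stop("polygon area must be > 0")
  structure(list(class_id = as.integer(class_id),
                 polygon = unname(polygon),
                 bbox = c(min(polygon[, 1L]), min(polygon[, 2L]),
                          max(polygon[, 1L]), max(polygon[, 2L]))),
            class = "instance_annotation")
}

# Shoelace area of a normalized polygon.
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' An image with its instance annotations
#'
#' @param image H x W x 3 numeric array, values in `[0, 1]`.
#' @param instances list of [instance_annotation()] objects.
#' @param source_id free-text provenance tag.
#' @return an `image_sample`.
#' @export
image_sample <- function(image, instances = list(), source_id = "") {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (d[1L] < 1L || d[2L] < 1L) stop("image must be at least 1 x 1")
  for (inst in instances)
    if (!inherits(inst, "instance_annotation"))
      stop("instances must be instance_annotation objects")
  structure(list(image = image, instances = instances,
                 source_id = source_id),
            class = "image_sample")
}

#' Dataset split fractions
#'
#' @param train,test,validation non-negative fractions summing to 1;
#'   defaults 0.70 / 0.20 / 0.10.
#' @return a `split_fractions` vector.
#' @export
split_fractions <- function(train = 0.70, test = 0.20, validation = 0.10) {
  f <- c(train = train, test = test, validation = validation)
  if (any(f < 0)) stop("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(f, class = "split_fractions")
}

# ---- YOLO-segmentation label text ------------------------------------------

parse_yolo_line <- function(line, lineno) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop("label line ", lineno, ": non-numeric token")
  cls <- vals[1L]
  coords <- vals[-1L]
  if (cls != round(cls) || !cls %in% c(0, 1))
    stop("label line ", lineno, ": unknown class ", cls)
  if (length(coords) %% 2L != 0L)
    stop("label line ", lineno, ": odd coordinate count")
  if (length(coords) < 6L)
    stop("label line ", lineno, ": polygon needs at least 3 vertices")
  if (any(coords < 0 | coords > 1))
    stop("label line ", lineno, ": coordinate outside [0, 1]")
  instance_annotation(as.integer(cls),
                      matrix(coords, ncol = 2L, byrow = TRUE))
}

#' Read / write YOLO-segmentation labels
#'
#' The label text format is one instance per line:
#' `class x1 y1 x2 y2 ...` with normalized coordinates. `read_yolo_seg()`
#' pairs a label file with its PNG image; `write_yolo_seg()` serializes
#' coordinates at 6 decimals so that read and write round-trip bit-exactly.
#'
#' @param label_path path to the label text file.
#' @param image_path path to the PNG image.
#' @return an [image_sample()].
#' @export
read_yolo_seg <- function(label_path, image_path) {
  img <- read_image(image_path)
  lines <- if (file.exists(label_path)) readLines(label_path) else character(0)
  lines <- lines[nzchar(trimws(lines))]
  insts <- lapply(seq_along(lines), function(i)
    parse_yolo_line(lines[i], i))
  image_sample(img, insts, source_id = basename(image_path))
}

#' @rdname read_yolo_seg
#' @param sample an [image_sample()].
#' @return `write_yolo_seg()`: the label path, invisibly.
#' @export
write_yolo_seg <- function(sample, label_path) {
  lines <- vapply(sample$instances, function(inst) {
    paste(c(inst$class_id,
            sprintf("%.6f", as.vector(t(inst$polygon)))),
          collapse = " ")
  }, "")
  writeLines(lines, label_path)
  invisible(label_path)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package")
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- aperm(img, c(2L, 1L, 3L))   # EBImage is x-major
  } else {
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# ---- COCO instance JSON ----------------------------------------------------

#' Export / import COCO instance annotations
#'
#' Writes the standard `images` / `annotations` / `categories` structure
#' with polygon segmentations in absolute pixel coordinates; boxes are
#' `[x, y, width, height]`.
#'
#' @param samples list of [image_sample()]; names (or source ids) become
#'   file names.
#' @param path output JSON path.
#' @return `write_coco_json()`: the path, invisibly; `read_coco_json()`:
#'   a list of per-image instance lists (normalized polygons).
#' @export
write_coco_json <- function(samples, path) {
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    d <- dim(s$image)
    fn <- if (nzchar(s$source_id)) s$source_id else sprintf("img_%05d", i)
    images[[i]] <- list(id = i, file_name = fn,
                        height = d[1L], width = d[2L])
    for (inst in s$instances) {
      aid <- aid + 1L
      px <- inst$polygon[, 1L] * d[2L]
      py <- inst$polygon[, 2L] * d[1L]
      bb <- c(min(px), min(py), max(px) - min(px), max(py) - min(py))
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = inst$class_id + 1L,
        segmentation = list(as.vector(rbind(px, py))),
        bbox = bb, area = abs(polygon_area(cbind(px, py))), iscrowd = 0L)
    }
  }
  out <- list(
    images = images, annotations = annotations,
    categories = lapply(seq_along(CLASS_NAMES), function(k)
      list(id = k, name = CLASS_NAMES[k])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_json
#' @export
read_coco_json <- function(path) {
  cc <- jsonlite::read_json(path)
  imgs <- setNames(cc$images, vapply(cc$images, function(im)
    as.character(im$id), ""))
  out <- lapply(cc$images, function(im)
    list(file_name = im$file_name, height = im$height, width = im$width,
         instances = list()))
  names(out) <- names(imgs)
  for (an in cc$annotations) {
    im <- imgs[[as.character(an$image_id)]]
    seg <- unlist(an$segmentation[[1L]])
    poly <- cbind(seg[c(TRUE, FALSE)] / im$width,
                  seg[c(FALSE, TRUE)] / im$height)
    poly <- pmin(pmax(poly, 0), 1)
    inst <- instance_annotation(an$category_id - 1L, poly)
    k <- as.character(an$image_id)
    out[[k]]$instances <- c(out[[k]]$instances, list(inst))
  }
  out
}

# ---- masks -----------------------------------------------------------------

#' Rasterize a normalized polygon to a binary mask
#'
#' Even-odd fill rule sampled at pixel centers: pixel (x, y) is foreground
#' iff its center (x + 0.5, y + 0.5) lies inside the denormalized polygon.
#'
#' @param polygon n x 2 normalized vertex matrix.
#' @param height,width output raster size.
#' @return H x W integer matrix (1 = inside). A degenerate (zero-area)
#'   polygon yields an empty mask with a warning.
#' @export
polygon_to_mask <- function(polygon, height, width) {
  polygon <- as.matrix(polygon)
  px <- polygon[, 1L] * width
  py <- polygon[, 2L] * height
  if (nrow(polygon) < 3L || abs(polygon_area(cbind(px, py))) < 1e-9) {
    warning("degenerate polygon; returning empty mask")
    return(matrix(0L, height, width))
  }
  m <- cpp_polygon_fill(px, py, as.integer(height), as.integer(width))
  dim(m) <- c(height, width)
  m
}

#' Write a binary mask as PNG
#'
#' @param mask H x W matrix, nonzero = foreground.
#' @param path output path; foreground is written as 255, background 0.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Resize a sample to a square raster
#'
#' Default is a direct anisotropic bilinear resize to `size` x `size`;
#' normalized polygon coordinates are unchanged by construction. With
#' `letterbox = TRUE` the aspect ratio is preserved, gray borders pad the
#' short side, and polygons are remapped accordingly.
#'
#' @param sample an [image_sample()].
#' @param size output side length.
#' @param letterbox preserve aspect ratio with padding instead.
#' @return resized [image_sample()].
#' @export
resize_to_square <- function(sample, size = 640L, letterbox = FALSE) {
  if (size <= 0L) stop("size must be positive")
  d <- dim(sample$image)
  chw <- aperm(sample$image, c(3L, 1L, 2L))
  if (!letterbox) {
    out <- bilinear_resize(chw, size, size)
    img <- aperm(out, c(2L, 3L, 1L))
    return(image_sample(img, sample$instances, sample$source_id))
  }
  sc <- min(size / d[1L], size / d[2L])
  nh <- max(1L, round(d[1L] * sc)); nw <- max(1L, round(d[2L] * sc))
  out <- bilinear_resize(chw, nh, nw)
  img <- array(0.5, c(size, size, 3L))
  oy <- (size - nh) %/% 2L; ox <- (size - nw) %/% 2L
  img[oy + seq_len(nh), ox + seq_len(nw), ] <- aperm(out, c(2L, 3L, 1L))
  insts <- lapply(sample$instances, function(inst) {
    p <- inst$polygon
    p[, 1L] <- (p[, 1L] * d[2L] * sc + ox) / size
    p[, 2L] <- (p[, 2L] * d[1L] * sc + oy) / size
    instance_annotation(inst$class_id, pmin(pmax(p, 0), 1))
  })
  image_sample(img, insts, sample$source_id)
}

# ---- dataset splitting -----------------------------------------------------

#' Split a dataset into train / test / validation partitions
#'
#' Sizes are `round(n * f_train)` and `round(n * f_test)` with the remainder
#' going to validation, so the canonical 0.70/0.20/0.10 fractions reproduce
#' exactly proportioned splits (e.g. 280 -> 196/56/28). Assignment is a
#' uniform random permutation, a deterministic function of `seed`. With
#' `stratify_by`, the same rule is applied within each group and the
#' partitions are concatenated (per-acquisition-setup stratification).
#'
#' @param samples list (or vector) of items to split.
#' @param fractions a [split_fractions()].
#' @param seed integer RNG seed.
#' @param stratify_by optional grouping factor of the same length.
#' @return list with `$train`, `$test`, `$validation` (same type as input),
#'   plus `$indices` giving the original positions.
#' @export
split_dataset <- function(samples, fractions = split_fractions(),
                          seed = 0L, stratify_by = NULL) {
  n <- length(samples)
  if (!is.null(stratify_by)) {
    stopifnot(length(stratify_by) == n)
    groups <- split(seq_len(n), stratify_by)
    idx <- list(train = integer(0), test = integer(0),
                validation = integer(0))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      sub <- split_indices(length(g), fractions, seed + gi)
      idx$train <- c(idx$train, g[sub$train])
      idx$test <- c(idx$test, g[sub$test])
      idx$validation <- c(idx$validation, g[sub$validation])
    }
  } else {
    idx <- split_indices(n, fractions, seed)
  }
  list(train = samples[idx$train], test = samples[idx$test],
       validation = samples[idx$validation], indices = idx)
}

split_indices <- function(n, fractions, seed) {
  if (n == 0L)
    return(list(train = integer(0), test = integer(0),
                validation = integer(0)))
  n_train <- round(n * fractions[["train"]])
  n_test <- round(n * fractions[["test"]])
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       validation = sort(perm[tail(seq_len(n), n - n_train - n_test)]))
}
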