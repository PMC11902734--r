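# Synthetic orchard-scene generator with exact ground truth.
#
# Scenes emulate the structure of fruit-and-stem imagery: large shaded
# elliptical fruits, each carrying one thin curved stem at its top boundary
# (stems occupy a far smaller area than fruits), over varied backgrounds
# and illumination. Every instance is painted from the exact polygon that
# is emitted as its ground truth, so rasterized annotation masks and painted
# regions coincide up to stem-over-apple overdraw.

#' Scene generator configuration
#'
#' All stochastic quantities are sampled uniformly from the given ranges.
#'
#' @param image_size square canvas side, >= 64 (320 default for desk-scale
#'   work, 640 for full-scale).
#' @param n_apples integer range of fruit count per scene, within 1..3.
#' @param apple_radius_frac range of fruit radius / image size, within
#'   0.12..0.30.
#' @param stem_length_frac range of stem length / image size, within
#'   0.05..0.15.
#' @param stem_width_px integer range of stem thickness in pixels, within
#'   2..6 (narrowed automatically if needed to keep each stem's area under a
#'   quarter of its fruit's area).
#' @param background_mode "plain", "gradient", "textured", "dark" (mirroring
#'   open-table / chamber / turntable acquisition variety), or "mixed" to
#'   sample one of the four per scene.
#' @param occlusion_prob probability that a stem root dips inside its fruit,
#'   so the fruit outline is partially overdrawn by the stem.
#' @param illumination_gain global brightness-gain range.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = 320L,
                         n_apples = c(1L, 3L),
                         apple_radius_frac = c(0.12, 0.30),
                         stem_length_frac = c(0.05, 0.15),
                         stem_width_px = c(2L, 6L),
                         background_mode = "mixed",
                         occlusion_prob = 0.15,
                         illumination_gain = c(0.6, 1.4)) {
  chk_range <- function(r, lo, hi, nm) {
    if (length(r) != 2L || r[1L] > r[2L])
      stop(nm, " must be a non-empty range c(lo, hi)")
    if (r[1L] < lo - 1e-9 || r[2L] > hi + 1e-9)
      stop(nm, " must lie within [", lo, ", ", hi, "]")
  }
  if (image_size < 64L) stop("image_size must be >= 64")
  chk_range(n_apples, 1, 3, "n_apples")
  chk_range(apple_radius_frac, 0.12, 0.30, "apple_radius_frac")
  chk_range(stem_length_frac, 0.05, 0.15, "stem_length_frac")
  chk_range(stem_width_px, 2, 6, "stem_width_px")
  if (!background_mode %in% c("plain", "gradient", "textured", "dark",
                              "mixed"))
    stop("unknown background_mode: ", background_mode)
  if (occlusion_prob < 0 || occlusion_prob > 1)
    stop("occlusion_prob must be in [0, 1]")
  chk_range(illumination_gain, 0.6, 1.4, "illumination_gain")
  structure(list(image_size = as.integer(image_size),
                 n_apples = as.integer(n_apples),
                 apple_radius_frac = apple_radius_frac,
                 stem_length_frac = stem_length_frac,
                 stem_width_px = as.integer(stem_width_px),
                 background_mode = background_mode,
                 occlusion_prob = occlusion_prob,
                 illumination_gain = illumination_gain),
            class = "scene_config")
}

runif1 <- function(r) runif(1L, r[1L], r[2L])

# Quadratic Bezier outline of a thick curved stem; returns the polygon in
# pixel coordinates (anticlockwise: left side out, right side back).
stem_polygon <- function(p0, dir, len, width, curl, n = 12L) {
  p2 <- p0 + len * dir
  nrm <- c(-dir[2L], dir[1L])
  p1 <- (p0 + p2) / 2 + curl * len * nrm
  t <- seq(0, 1, length.out = n)
  bx <- (1 - t)^2 * p0[1L] + 2 * (1 - t) * t * p1[1L] + t^2 * p2[1L]
  by <- (1 - t)^2 * p0[2L] + 2 * (1 - t) * t * p1[2L] + t^2 * p2[2L]
  dx <- 2 * (1 - t) * (p1[1L] - p0[1L]) + 2 * t * (p2[1L] - p1[1L])
  dy <- 2 * (1 - t) * (p1[2L] - p0[2L]) + 2 * t * (p2[2L] - p1[2L])
  nl <- sqrt(dx^2 + dy^2)
  nx <- -dy / nl; ny <- dx / nl
  hw <- width / 2
  left <- cbind(bx + nx * hw, by + ny * hw)
  right <- cbind(bx - nx * hw, by - ny * hw)
  rbind(left, right[rev(seq_len(n)), ])
}

# Sample one fruit + stem geometry; coordinates in pixels. `rmax_frac`
# truncates the radius range so several fruits can share the canvas
# (the first fruit of a scene always draws from the full range).
sample_fruit_geom <- function(cfg, rmax_frac = cfg$apple_radius_frac[2L]) {
  s <- cfg$image_size
  rr <- c(cfg$apple_radius_frac[1L],
          max(cfg$apple_radius_frac[1L], rmax_frac))
  rx <- runif1(rr) * s
  ry <- rx * runif(1L, 0.85, 1.1)
  len <- runif1(cfg$stem_length_frac) * s
  width <- runif(1L, cfg$stem_width_px[1L], cfg$stem_width_px[2L])
  # constructive cap: keep stem area well below a quarter of fruit area
  amax <- 0.2 * pi * rx * ry
  if (len * width > amax) width <- max(1.5, amax / len)
  if (len * width > amax) len <- amax / width
  phi <- runif(1L, -0.4, 0.4)            # stem tilt from vertical
  dirv <- c(sin(phi), -cos(phi))
  tip_reach <- len + width
  cx <- runif(1L, rx + 2, s - rx - 2)
  cy <- runif(1L, ry + tip_reach + 3, s - ry - 2)
  dip <- if (runif(1L) < cfg$occlusion_prob)
    runif(1L, 0.05, 0.25) * len else 0
  list(cx = cx, cy = cy, rx = rx, ry = ry, len = len, width = width,
       dirv = dirv, curl = runif(1L, -0.25, 0.25), dip = dip)
}

geom_fits <- function(a, placed) {
  for (b in placed) {
    d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
    ra <- max(a$rx, a$ry); rb <- max(b$rx, b$ry)
    if (d < ra + rb + 3) return(FALSE)
    # stem corridors (circle over the stem span) must clear the other fruit
    sa <- c(a$cx + a$dirv[1L] * a$len / 2, a$cy - a$ry + a$dirv[2L] * a$len / 2)
    sb <- c(b$cx + b$dirv[1L] * b$len / 2, b$cy - b$ry + b$dirv[2L] * b$len / 2)
    if (sqrt(sum((sa - c(b$cx, b$cy))^2)) < a$len / 2 + a$width + rb + 2)
      return(FALSE)
    if (sqrt(sum((sb - c(a$cx, a$cy))^2)) < b$len / 2 + b$width + ra + 2)
      return(FALSE)
  }
  TRUE
}

paint_instance <- function(img, mask_idx, s, base, shade) {
  for (k in 1:3) {
    lin <- mask_idx + (k - 1L) * s * s
    img[lin] <- pmin(pmax(base[k] * shade +
                            rnorm(length(mask_idx), 0, 0.02), 0), 1)
  }
  img
}

make_background <- function(mode, s) {
  if (mode == "mixed")
    mode <- sample(c("plain", "gradient", "textured", "dark"), 1L)
  base <- switch(mode,
    plain = array(rep(runif(3L, 0.35, 0.75), each = s * s), c(s, s, 3L)),
    dark = array(rep(runif(3L, 0.02, 0.12), each = s * s), c(s, s, 3L)),
    gradient = {
      c1 <- runif(3L, 0.2, 0.8); c2 <- runif(3L, 0.2, 0.8)
      ang <- runif(1L, 0, 2 * pi)
      xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)
      ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)
      t <- (cos(ang) * xs + sin(ang) * ys) / s
      t <- (t - min(t)) / max(1e-9, diff(range(t)))
      arr <- array(0, c(s, s, 3L))
      for (k in 1:3) arr[, , k] <- c1[k] * (1 - t) + c2[k] * t
      arr
    },
    textured = {
      cbase <- runif(3L, 0.25, 0.65)
      coarse <- array(rnorm(3L * 8L * 8L, 0, 0.12), c(3L, 8L, 8L))
      fine <- bilinear_resize(coarse, s, s)
      arr <- array(0, c(s, s, 3L))
      for (k in 1:3) arr[, , k] <- pmin(pmax(cbase[k] + fine[k, , ], 0), 1)
      arr
    })
  base
}

APPLE_PALETTE <- list(red = c(0.78, 0.15, 0.12),
                      green = c(0.45, 0.68, 0.20),
                      yellow = c(0.85, 0.75, 0.20))

#' Generate one synthetic scene
#'
#' Deterministic for a fixed (config, seed). Each fruit is a shaded ellipse
#' polygonized at 48 vertices; each fruit carries exactly one stem, a thick
#' quadratic-curve polyline attached at the fruit's top boundary (optionally
#' dipping inside it). Ground-truth polygons are exact by construction:
#' instances are painted from the very polygons that are emitted.
#'
#' @param config a [scene_config()].
#' @param rng_seed integer seed.
#' @return an [image_sample()] with alternating apple/stem instances.
#' @export
generate_scene <- function(config, rng_seed) {
  with_seed(rng_seed, generate_scene_impl(config, rng_seed))
}

generate_scene_impl <- function(cfg, rng_seed) {
  s <- cfg$image_size
  n_ap <- if (cfg$n_apples[1L] == cfg$n_apples[2L]) cfg$n_apples[1L] else
    sample(cfg$n_apples[1L]:cfg$n_apples[2L], 1L)
  # whole-scene rejection sampling: a scene attempt places fruits greedily
  # (later fruits draw from a truncated radius range so several can share
  # the canvas); if any fruit fails, the entire layout is redrawn
  geoms <- NULL
  for (attempt in seq_len(100L)) {
    cand <- list()
    for (i in seq_len(n_ap)) {
      rmax <- cfg$apple_radius_frac[2L] / sqrt(i)
      ok <- FALSE
      for (try_i in seq_len(30L)) {
        g <- sample_fruit_geom(cfg, rmax)
        if (geom_fits(g, cand)) {
          cand <- c(cand, list(g))
          ok <- TRUE
          break
        }
      }
      if (!ok) break
    }
    if (length(cand) == n_ap) {
      geoms <- cand
      break
    }
  }
  if (is.null(geoms))
    stop("could not place ", n_ap,
         " fruits without overlap in 100 attempts")
  img <- make_background(cfg$background_mode, s)
  instances <- list()
  theta <- seq(0, 2 * pi, length.out = 49L)[-49L]
  for (g in geoms) {
    apoly <- cbind(g$cx + g$rx * cos(theta), g$cy + g$ry * sin(theta))
    apoly_n <- pmin(pmax(apoly / s, 0), 1)
    amask <- polygon_to_mask(apoly_n, s, s)
    aidx <- which(amask == 1L)
    yy <- (aidx - 1L) %% s + 0.5
    xx <- (aidx - 1L) %/% s + 0.5
    hx <- g$cx - 0.35 * g$rx; hy <- g$cy - 0.35 * g$ry
    dist <- sqrt(((xx - hx) / g$rx)^2 + ((yy - hy) / g$ry)^2)
    shade <- pmin(pmax(1.15 - 0.45 * dist, 0.35), 1.15)
    base <- unlist(APPLE_PALETTE[[sample(length(APPLE_PALETTE), 1L)]])
    base <- pmin(pmax(base + rnorm(3L, 0, 0.05), 0), 1)
    img <- paint_instance(img, aidx, s, base, shade)

    root <- c(g$cx, g$cy - g$ry + g$dip)
    spoly <- stem_polygon(root, g$dirv, g$len + g$dip, g$width, g$curl)
    spoly_n <- pmin(pmax(spoly / s, 0), 1)
    smask <- polygon_to_mask(spoly_n, s, s)
    sidx <- which(smask == 1L)
    sbase <- pmin(pmax(c(0.38, 0.26, 0.10) + rnorm(3L, 0, 0.04), 0), 1)
    if (length(sidx))
      img <- paint_instance(img, sidx, s, sbase, 1)
    instances <- c(instances,
                   list(instance_annotation(0L, apoly_n),
                        instance_annotation(1L, spoly_n)))
  }
  gain <- runif1(cfg$illumination_gain)
  img <- pmin(pmax(img * gain, 0), 1)
  image_sample(img, instances,
               source_id = sprintf("synthetic_seed%d", rng_seed))
}

#' Generate a list of scenes in memory
#'
#' Per-scene seed is `seed + i`, so any scene is regenerable in isolation.
#'
#' @param n scene count.
#' @param config a [scene_config()].
#' @param seed global seed.
#' @return list of [image_sample()].
#' @export
generate_scenes <- function(n, config = scene_config(), seed = 0L) {
  lapply(seq_len(n), function(i) generate_scene(config, seed + i))
}

#' Generate a dataset on disk
#'
#' Writes `n` PNG images with matching YOLO-segmentation label files and a
#' JSON manifest recording paths and per-scene seeds (`seed + i`);
#' regenerating with identical arguments reproduces identical files.
#'
#' @param n number of scenes.
#' @param config a [scene_config()].
#' @param seed global seed.
#' @param out_dir output directory.
#' @return the manifest list (`$entries` has image, label, seed per scene).
#' @export
generate_dataset <- function(n, config = scene_config(), seed = 0L,
                             out_dir) {
  if (n < 0L) stop("n must be >= 0")
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(config, seed + i)
    img_name <- sprintf("img_%05d.png", i)
    lbl_name <- sprintf("img_%05d.txt", i)
    write_image(sc$image, file.path(out_dir, img_name))
    write_yolo_seg(sc, file.path(out_dir, lbl_name))
    entries[[i]] <- list(image = img_name, label = lbl_name,
                         seed = seed + i)
  }
  manifest <- list(n = n, seed = seed, image_size = config$image_size,
                   classes = CLASS_NAMES, entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Load a generated dataset back into memory
#'
#' @param dir directory holding `manifest.json` plus the image/label files.
#' @return list of [image_sample()].
#' @export
load_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  lapply(man$entries, function(e)
    read_yolo_seg(file.path(dir, e$label), file.path(dir, e$image)))
}
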