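# Full detector assembly: backbone with ghost-bottleneck downsampling,
# neck with global attention, anchor-free decoupled segmentation head with
# mask prototypes.

NOMINAL_CHANNELS <- c(64L, 128L, 256L, 512L, 1024L)
NOMINAL_DEPTHS_BB <- c(3L, 6L, 6L, 3L)        # backbone C2f iterations
NOMINAL_DEPTHS_NECK <- c(3L, 3L, 3L, 1L)      # neck C2f iterations

scale_channels <- function(c, width) {
  s <- as.integer(pmax(8L, round(c * width / 4) * 4L))
  s
}

scale_depth <- function(n, depth) as.integer(pmax(1L, round(n * depth)))

#' Model specification
#'
#' Describes the network scale. The nominal scale (`width_multiple = 1`,
#' `depth_multiple = 1`) carries 64...1024 backbone channels with C2f
#' iteration counts 3/6/6/3 (backbone) and 3/3/3/1 (neck). The `"tiny"`
#' preset (0.25/0.34, 320 px input) is a desk-scale reduction for CPU
#' experiments and tests; it is an extension of the nominal design, not an
#' alternative published scale.
#'
#' @param num_classes number of object classes (fruit = 0, stem = 1).
#' @param input_size square input resolution, divisible by 32.
#' @param width_multiple,depth_multiple channel and iteration scaling.
#' @param reg_max number of distribution bins per box side.
#' @param n_prototypes mask prototype count.
#' @param se_mode squeeze-excitation placement in ghost bottlenecks:
#'   "stride2" (default; all three downsampling bottlenecks), "all", "none".
#' @param preset "full" or "tiny"; "tiny" overrides the multiples to
#'   0.25/0.34 and the input size to 320 unless given explicitly.
#' @return a `model_spec` list including the realized per-stage channels.
#' @export
model_spec <- function(num_classes = 2L, input_size = NULL,
                       width_multiple = NULL, depth_multiple = NULL,
                       reg_max = 16L, n_prototypes = 32L,
                       se_mode = c("stride2", "all", "none"),
                       preset = c("full", "tiny")) {
  preset <- match.arg(preset)
  se_mode <- match.arg(se_mode)
  if (is.null(width_multiple))
    width_multiple <- if (preset == "tiny") 0.25 else 1.0
  if (is.null(depth_multiple))
    depth_multiple <- if (preset == "tiny") 0.34 else 1.0
  if (is.null(input_size))
    input_size <- if (preset == "tiny") 320L else 640L
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  ch <- scale_channels(NOMINAL_CHANNELS, width_multiple)
  if (any(ch < 8L) || any(ch %% 4L != 0L))
    stop("scaled channels must be >= 8 and divisible by 4")
  spec <- list(
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    width_multiple = width_multiple,
    depth_multiple = depth_multiple,
    reg_max = as.integer(reg_max),
    n_prototypes = as.integer(n_prototypes),
    se_mode = se_mode,
    strides = c(8L, 16L, 32L),
    channels = ch,
    depths_backbone = scale_depth(NOMINAL_DEPTHS_BB, depth_multiple),
    depths_neck = scale_depth(NOMINAL_DEPTHS_NECK, depth_multiple))
  structure(spec, class = "model_spec")
}

#' Build the segmentation model
#'
#' Assembles the full layer graph: a backbone whose three stride-2
#' downsampling stages are ghost bottlenecks (or plain stride-2 convolutions
#' when `downsample = "conv"`, kept for parameter-count comparisons), a
#' pyramid neck with two global attention modules, and a decoupled
#' anchor-free head with mask prototypes read from the stride-8 scale.
#'
#' @param spec a [model_spec()].
#' @param downsample "ghost" (default) or "conv".
#' @return a `seg_model` list with `$spec`, `$nodes` (named graph), `$head`.
#' @export
build_model <- function(spec, downsample = c("ghost", "conv")) {
  downsample <- match.arg(downsample)
  ch <- spec$channels
  db <- spec$depths_backbone
  dn <- spec$depths_neck
  use_se <- spec$se_mode %in% c("stride2", "all")
  down <- function(cin, cout) {
    if (downsample == "ghost")
      new_gbneck(cin, cout, s = 2L, use_se = use_se)
    else new_cbs(cin, cout, k = 3L, s = 2L)
  }
  node <- function(name, from, mod = NULL, op = "mod", out_ch = NA_integer_)
    list(name = name, from = from, mod = mod, op = op,
         out_ch = as.integer(out_ch))
  nodes <- list(
    node("input", character(0), op = "input", out_ch = 3L),
    node("conv1", "input", {
      m <- new_cbs(3L, ch[1], k = 3L, s = 2L)
      m$skip_gx <- TRUE  # first layer: input gradient is never consumed
      m
    }, out_ch = ch[1]),
    node("conv2", "conv1", new_cbs(ch[1], ch[2], k = 3L, s = 2L),
         out_ch = ch[2]),
    node("c2f1", "conv2", new_c2f(ch[2], ch[2], n = db[1]), out_ch = ch[2]),
    node("gb1", "c2f1", down(ch[2], ch[3]), out_ch = ch[3]),
    node("c2f2", "gb1", new_c2f(ch[3], ch[3], n = db[2]), out_ch = ch[3]),
    node("gb2", "c2f2", down(ch[3], ch[4]), out_ch = ch[4]),
    node("c2f3", "gb2", new_c2f(ch[4], ch[4], n = db[3]), out_ch = ch[4]),
    node("gb3", "c2f3", down(ch[4], ch[5]), out_ch = ch[5]),
    node("c2f4", "gb3", new_c2f(ch[5], ch[5], n = db[4]), out_ch = ch[5]),
    node("sppf", "c2f4", new_sppf(ch[5], ch[5], k = 5L), out_ch = ch[5]),
    node("up1", "sppf", new_upsample2(), out_ch = ch[5]),
    node("cat1", c("up1", "c2f3"), op = "concat", out_ch = ch[5] + ch[4]),
    node("c2f5", "cat1", new_c2f(ch[5] + ch[4], ch[4], n = dn[1],
                                 shortcut = FALSE), out_ch = ch[4]),
    node("up2", "c2f5", new_upsample2(), out_ch = ch[4]),
    node("cat2", c("up2", "c2f2"), op = "concat", out_ch = ch[4] + ch[3]),
    node("c2f6", "cat2", new_c2f(ch[4] + ch[3], ch[3], n = dn[2],
                                 shortcut = FALSE), out_ch = ch[3]),
    node("gam1", "c2f6", new_gam(ch[3]), out_ch = ch[3]),
    node("conv3", "gam1", new_cbs(ch[3], ch[3], k = 3L, s = 2L),
         out_ch = ch[3]),
    node("cat3", c("conv3", "c2f5"), op = "concat", out_ch = ch[3] + ch[4]),
    node("c2f7", "cat3", new_c2f(ch[3] + ch[4], ch[4], n = dn[3],
                                 shortcut = FALSE), out_ch = ch[4]),
    node("gam2", "c2f7", new_gam(ch[4]), out_ch = ch[4]),
    node("conv4", "gam2", new_cbs(ch[4], ch[4], k = 3L, s = 2L),
         out_ch = ch[4]),
    node("cat4", c("conv4", "sppf"), op = "concat", out_ch = ch[4] + ch[5]),
    node("c2f8", "cat4", new_c2f(ch[4] + ch[5], ch[5], n = dn[4],
                                 shortcut = FALSE), out_ch = ch[5]))
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  head <- build_head(spec, c(ch[3], ch[4], ch[5]))
  structure(list(spec = spec, downsample = downsample, nodes = nodes,
                 head = head, head_from = c("gam1", "gam2", "c2f8")),
            class = "seg_model")
}

build_head <- function(spec, scale_ch) {
  h <- new_mod("head")
  nc <- spec$num_classes
  rm4 <- 4L * spec$reg_max
  npr <- spec$n_prototypes
  h$sub$scales <- lapply(scale_ch, function(ci) {
    hid <- max(16L, ci %/% 4L)
    lin <- function(cin, cout)
      new_cbs(cin, cout, k = 1L, act = "linear", norm = FALSE, bias = TRUE)
    sc <- new_mod("headscale")
    sc$sub$box <- new_seq(new_cbs(ci, hid, k = 3L), lin(hid, rm4))
    sc$sub$cls <- new_seq(new_cbs(ci, hid, k = 3L), lin(hid, nc))
    sc$sub$coef <- new_seq(new_cbs(ci, hid, k = 3L), lin(hid, npr))
    # rare-object prior keeps the initial classification loss tame
    sc$sub$cls$sub[[2L]]$par$b[] <- log(0.01 / 0.99)
    sc
  })
  cp3 <- scale_ch[1L]
  hp <- max(npr, cp3 %/% 2L)
  h$sub$proto <- new_seq(new_cbs(cp3, hp, k = 3L),
                         new_cbs(hp, npr, k = 1L, act = "linear",
                                 norm = FALSE, bias = TRUE))
  h
}

#' Run the model forward
#'
#' @param model a [build_model()] result.
#' @param x input batch (3, H, W, N), values in `[0, 1]`, H = W =
#'   `spec$input_size`.
#' @param training if `TRUE`, batch-norm uses batch statistics and every
#'   module caches what backpropagation needs.
#' @return `raw_predictions`: `$scales` (per stride: `$box` 4*reg_max
#'   channels of distribution logits, `$cls` class logits, `$coef` mask
#'   coefficients), `$proto` prototypes at stride 8, `$strides`,
#'   `$input_size`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  sz <- model$spec$input_size
  if (length(d) != 4L || d[1L] != 3L || d[2L] != sz || d[3L] != sz)
    stop("input must be (3, ", sz, ", ", sz, ", N)")
  xt <- ft_handle(cpp_ft_new(x, dim(x)), dim(x))
  outs <- list()
  for (nd in model$nodes) {
    outs[[nd$name]] <- switch(nd$op,
      input = xt,
      concat = ft_cat(outs[nd$from]),
      mod = mod_fwd(nd$mod, outs[[nd$from]], training))
  }
  xs <- outs[model$head_from]
  hd <- model$head
  scales <- vector("list", 3L)
  for (i in 1:3) {
    sc <- hd$sub$scales[[i]]
    scales[[i]] <- list(
      box = ft_array(mod_fwd(sc$sub$box, xs[[i]], training)),
      cls = ft_array(mod_fwd(sc$sub$cls, xs[[i]], training)),
      coef = ft_array(mod_fwd(sc$sub$coef, xs[[i]], training)))
  }
  proto <- ft_array(mod_fwd(hd$sub$proto, xs[[1L]], training))
  structure(list(scales = scales, proto = proto,
                 strides = model$spec$strides,
                 input_size = sz, n = d[4L]),
            class = "raw_predictions")
}

# Backpropagate gradients w.r.t. the raw prediction maps through the whole
# graph, accumulating parameter gradients. `grads` mirrors the
# raw_predictions structure.
model_backward <- function(model, grads) {
  hd <- model$head
  as_ft <- function(g) ft_handle(cpp_ft_new(g, dim(g)), dim(g))
  gx_head <- vector("list", 3L)
  for (i in 1:3) {
    sc <- hd$sub$scales[[i]]
    g <- mod_bwd(sc$sub$box, as_ft(grads$scales[[i]]$box))
    g <- ft_add(g, mod_bwd(sc$sub$cls, as_ft(grads$scales[[i]]$cls)))
    g <- ft_add(g, mod_bwd(sc$sub$coef, as_ft(grads$scales[[i]]$coef)))
    gx_head[[i]] <- g
  }
  gx_head[[1L]] <- ft_add(gx_head[[1L]],
                          mod_bwd(hd$sub$proto, as_ft(grads$proto)))
  acc <- list()
  add_grad <- function(name, g) {
    acc[[name]] <<- if (is.null(acc[[name]])) g else ft_add(acc[[name]], g)
  }
  for (i in 1:3) add_grad(model$head_from[i], gx_head[[i]])
  for (nd in rev(model$nodes)) {
    g <- acc[[nd$name]]
    if (is.null(g)) next
    if (nd$op == "input") next
    if (nd$op == "concat") {
      sizes <- vapply(model$nodes[nd$from], `[[`, 0L, "out_ch")
      parts <- ft_split(g, sizes)
      for (i in seq_along(nd$from)) add_grad(nd$from[i], parts[[i]])
    } else {
      add_grad(nd$from, mod_bwd(nd$mod, g))
    }
  }
  invisible(NULL)
}

model_modules <- function(model) {
  mods <- lapply(Filter(function(nd) !is.null(nd$mod), model$nodes),
                 `[[`, "mod")
  c(mods, list(head = model$head))
}

model_leaves <- function(model)
  unlist(lapply(model_modules(model), mod_leaves), use.names = FALSE)

#' Model state and parameter counts
#'
#' `model_state()` returns every learnable parameter and batch-norm running
#' statistic as a flat named list; `model_load_state()` writes such a list
#' back; `model_n_params()` counts learnable parameters.
#'
#' @param model a `seg_model`.
#' @return named list / the model / integer count.
#' @export
model_state <- function(model) {
  st <- list()
  mods <- model_modules(model)
  for (nm in names(mods))
    st <- c(st, mod_state(mods[[nm]], paste0(nm, ".")))
  st
}

#' @rdname model_state
#' @param state a named list as returned by `model_state()`.
#' @export
model_load_state <- function(model, state) {
  mods <- model_modules(model)
  for (nm in names(mods)) mod_load_state(mods[[nm]], state, paste0(nm, "."))
  invisible(model)
}

#' @rdname model_state
#' @param part "all", "backbone", "neck" or "head".
#' @export
model_n_params <- function(model, part = "all") {
  backbone <- c("conv1", "conv2", "c2f1", "gb1", "c2f2", "gb2", "c2f3",
                "gb3", "c2f4", "sppf")
  mods <- model_modules(model)
  keep <- switch(part,
    all = names(mods),
    backbone = intersect(names(mods), backbone),
    neck = setdiff(names(mods), c(backbone, "head")),
    head = "head",
    stop("unknown part: ", part))
  sum(vapply(mods[keep], mod_n_params, 0))
}

#' Graph wiring table
#'
#' One row per graph node with its operation and comma-joined inputs;
#' the head row lists its three input nodes.
#'
#' @param model a `seg_model`.
#' @return data.frame with columns name, op, from.
#' @export
model_graph <- function(model) {
  df <- data.frame(
    name = vapply(model$nodes, `[[`, "", "name"),
    op = vapply(model$nodes, function(nd)
      if (nd$op != "mod") nd$op else nd$mod$type, ""),
    from = vapply(model$nodes, function(nd)
      paste(nd$from, collapse = ","), ""),
    stringsAsFactors = FALSE)
  rbind(df, data.frame(name = "head", op = "head",
                       from = paste(model$head_from, collapse = ",")))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `spec.json` (model specification),
#' `manifest.json` (parameter names, shapes and offsets) and `params.bin`
#' (little-endian doubles) - a framework-neutral flat archive.
#'
#' @param model a `seg_model`.
#' @param path checkpoint directory (created if needed).
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` a
#'   rebuilt `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  st <- model_state(model)
  lens <- vapply(st, length, 0L)
  manifest <- list(
    spec_file = "spec.json",
    names = names(st),
    shapes = lapply(st, function(p) if (is.null(dim(p))) length(p) else dim(p)),
    offsets = c(0L, cumsum(lens))[seq_along(st)])
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- model$spec
  sp$downsample <- model$downsample
  jsonlite::write_json(unclass(sp), file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "params.bin"), "wb")
  on.exit(close(con))
  for (p in st) writeBin(as.double(p), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sp <- jsonlite::read_json(file.path(path, "spec.json"),
                            simplifyVector = TRUE)
  spec <- model_spec(num_classes = sp$num_classes,
                     input_size = sp$input_size,
                     width_multiple = sp$width_multiple,
                     depth_multiple = sp$depth_multiple,
                     reg_max = sp$reg_max, n_prototypes = sp$n_prototypes,
                     se_mode = sp$se_mode)
  model <- build_model(spec, downsample = sp$downsample)
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  con <- file(file.path(path, "params.bin"), "rb")
  on.exit(close(con))
  st <- list()
  for (i in seq_along(man$names)) {
    shp <- unlist(man$shapes[[i]])
    v <- readBin(con, "double", n = prod(shp), size = 8L, endian = "little")
    if (length(shp) > 1L) dim(v) <- shp
    st[[man$names[i]]] <- v
  }
  model_load_state(model, st)
  model
}
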