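# Public block-level API.
#
# Each network block is exposed as a pure feature-map transform
# `block(x, cfg, params)`. Parameters travel as a flat named list of arrays
# (see [block_init()]); this is the same archive format used by model
# checkpoints, so blocks can be exercised and unit-tested in isolation.

#' Ghost module / ghost bottleneck configuration
#'
#' @param c1,c2 input and output channel counts.
#' @param r filter reduction ratio of the ghost module: the primary 1x1
#'   convolution produces `c2/r` channels and cheap depthwise operations
#'   generate the remaining `c2*(r-1)/r`.
#' @param k depthwise kernel size of the cheap operation (odd).
#' @param s stride, 1 or 2 (2 halves the spatial dimensions).
#' @param use_se whether a squeeze-and-excitation gate sits between the two
#'   ghost modules of a bottleneck.
#' @param norm,act whether convolutions carry batch normalization, and the
#'   activation used ("silu", "relu" or "linear"). Disabling both yields the
#'   bare linear-algebra form used by parameter-count comparisons.
#' @return a `ghost_config` list.
#' @export
ghost_config <- function(c1, c2, r = 2L, k = 3L, s = 1L, use_se = FALSE,
                         norm = TRUE, act = "silu") {
  if (c2 %% r != 0L) stop("c2 must be divisible by r")
  if (k %% 2L == 0L) stop("kernel size k must be odd")
  if (!s %in% c(1L, 2L)) stop("stride must be 1 or 2")
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2), r = as.integer(r),
                 k = as.integer(k), s = as.integer(s), use_se = use_se,
                 norm = norm, act = act),
            class = "ghost_config")
}

#' Squeeze-and-excitation configuration
#'
#' @param channels feature-map channels.
#' @param reduction bottleneck reduction of the two fully connected layers.
#' @return an `se_config` list.
#' @export
se_config <- function(channels, reduction = 4L) {
  if (channels %% reduction != 0L)
    stop("channels must be divisible by reduction")
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction)),
            class = "se_config")
}

#' Global attention module configuration
#'
#' @param channels feature-map channels.
#' @param reduction channel reduction of both the channel and spatial
#'   branches.
#' @param spatial_kernel odd kernel size of the two spatial-attention
#'   convolutions.
#' @return a `gam_config` list.
#' @export
gam_config <- function(channels, reduction = 4L, spatial_kernel = 7L) {
  if (channels %% reduction != 0L)
    stop("channels must be divisible by reduction")
  if (spatial_kernel %% 2L == 0L) stop("spatial kernel must be odd")
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "gam_config")
}

build_block <- function(kind, cfg) {
  switch(kind,
    ghost = new_ghost(cfg$c1, cfg$c2, r = cfg$r, k = cfg$k,
                      norm = cfg$norm, act = cfg$act),
    ghost_bottleneck = new_gbneck(cfg$c1, cfg$c2, r = cfg$r, k = cfg$k,
                                  s = cfg$s, use_se = cfg$use_se),
    se = new_changate(cfg$channels, cfg$reduction, delta = "relu"),
    gam = new_gam(cfg$channels, cfg$reduction, cfg$spatial_kernel),
    stop("unknown block kind: ", kind))
}

#' Initialize parameters for a block
#'
#' Draws randomly initialized parameters (He-scaled weights, unit batch-norm)
#' for a block, returned as a flat named list keyed by dotted hierarchical
#' names. Seed the R RNG beforehand for reproducibility.
#'
#' @param kind one of "ghost", "ghost_bottleneck", "se", "gam".
#' @param cfg the matching configuration object.
#' @return named list of numeric arrays.
#' @export
block_init <- function(kind, cfg) mod_state(build_block(kind, cfg))

run_block <- function(kind, cfg, x, params) {
  m <- build_block(kind, cfg)
  if (!is.null(params)) mod_load_state(m, params)
  y <- mod_fwd(m, ft_from_array(unclass(x)), training = FALSE)
  feature_map(drop_batch(ft_array(y)))
}

#' Ghost module
#'
#' A convolution substitute: a primary 1x1 convolution reduces the input to
#' `c2/r` channels, cheap depthwise operations generate the remaining ghost
#' features from it, and the two are concatenated to exactly `c2` channels at
#' unchanged spatial size.
#'
#' @param x feature map (C, H, W) with `cfg$c1` channels.
#' @param cfg a [ghost_config()].
#' @param params flat named parameter list from [block_init()]; `NULL` draws
#'   a fresh random initialization.
#' @return feature map with `cfg$c2` channels.
#' @export
ghost_module <- function(x, cfg, params = NULL) {
  if (dim(x)[1L] != cfg$c1)
    stop("input has ", dim(x)[1L], " channels, config expects ", cfg$c1)
  run_block("ghost", cfg, x, params)
}

#' Squeeze-and-excitation layer
#'
#' Global average pooling per channel, two fully connected layers
#' (ReLU between, sigmoid after), and per-channel rescaling of the input by
#' the resulting gate in (0, 1).
#'
#' @param x feature map with `cfg$channels` channels.
#' @param cfg an [se_config()].
#' @param params flat named parameter list (`w1`, `b1`, `w2`, `b2`).
#' @return gated feature map, same shape as the input.
#' @export
se_layer <- function(x, cfg, params = NULL) {
  if (dim(x)[1L] != cfg$channels)
    stop("input has ", dim(x)[1L], " channels, config expects ", cfg$channels)
  run_block("se", cfg, x, params)
}

#' Ghost bottleneck
#'
#' Residual block: ghost module, optional stride-2 depthwise downsampling,
#' optional squeeze-and-excitation gate, second ghost module; summed with an
#' identity shortcut (stride 1, matching channels) or a depthwise + 1x1
#' projection shortcut otherwise.
#'
#' @inheritParams ghost_module
#' @return feature map with `cfg$c2` channels; spatial dimensions are halved
#'   (ceiling) iff `cfg$s == 2`.
#' @export
ghost_bottleneck <- function(x, cfg, params = NULL) {
  if (dim(x)[1L] != cfg$c1)
    stop("input has ", dim(x)[1L], " channels, config expects ", cfg$c1)
  run_block("ghost_bottleneck", cfg, x, params)
}

#' Global attention module
#'
#' Sequential channel and spatial attention. The channel gate is a pooled
#' two-layer network (SiLU between, sigmoid after) multiplied into the input;
#' the spatial gate is two k x k convolutions (channel reduction then
#' restoration, sigmoid after) multiplied into the channel-attended map.
#' Both gates lie in (0, 1), so the output never exceeds the input in
#' magnitude.
#'
#' @param x feature map with `cfg$channels` channels.
#' @param cfg a [gam_config()].
#' @param params flat named parameter list.
#' @return feature map, same shape as the input.
#' @export
gam <- function(x, cfg, params = NULL) {
  if (dim(x)[1L] != cfg$channels)
    stop("input has ", dim(x)[1L], " channels, config expects ", cfg$channels)
  run_block("gam", cfg, x, params)
}

#' Standard convolution block
#'
#' Convolution + batch normalization + SiLU (both optional), the unit used
#' throughout the backbone and neck.
#'
#' @param x feature map (C, H, W).
#' @param out_channels output channels.
#' @param kernel,stride,padding convolution geometry; output spatial size is
#'   `floor((H + 2*padding - kernel)/stride) + 1`.
#' @param params flat named parameter list; `NULL` draws a random one.
#' @param norm,act normalization switch and activation name.
#' @return transformed feature map.
#' @export
conv_block <- function(x, out_channels, kernel = 3L, stride = 1L,
                       padding = (kernel - 1L) %/% 2L, params = NULL,
                       norm = TRUE, act = "silu") {
  d <- dim(x)
  if (d[2L] + 2L * padding < kernel || d[3L] + 2L * padding < kernel)
    stop("kernel exceeds padded input")
  m <- new_cbs(d[1L], out_channels, k = kernel, s = stride, p = padding,
               act = act, norm = norm)
  if (!is.null(params)) mod_load_state(m, params)
  feature_map(drop_batch(ft_array(mod_fwd(m, ft_from_array(unclass(x)),
                                          FALSE))))
}

#' C2f block (cross-stage partial bottleneck with 2 convolutions, faster)
#'
#' A 1x1 convolution splits the input into two halves; a chain of
#' `n_iterations` residual 3x3 bottlenecks processes one half; all
#' intermediates are concatenated and fused by a second 1x1 convolution.
#'
#' @inheritParams conv_block
#' @param n_iterations number of chained bottlenecks (>= 1).
#' @param shortcut whether the inner bottlenecks carry residual connections.
#' @return feature map with `out_channels` channels, spatial size preserved.
#' @export
c2f_block <- function(x, out_channels, n_iterations = 1L, params = NULL,
                      shortcut = TRUE) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  m <- new_c2f(dim(x)[1L], out_channels, n = n_iterations,
               shortcut = shortcut)
  if (!is.null(params)) mod_load_state(m, params)
  feature_map(drop_batch(ft_array(mod_fwd(m, ft_from_array(unclass(x)),
                                          FALSE))))
}

#' SPPF block (spatial pyramid pooling, fast)
#'
#' 1x1 reduction, three chained stride-1 max pools of equal kernel,
#' concatenation of all four maps, and a 1x1 expansion. Equivalent to
#' pooling at kernel sizes k, 2k-1, 3k-2 at constant resolution.
#'
#' @inheritParams conv_block
#' @param pool_kernel max-pool kernel size.
#' @return feature map with `out_channels` channels, spatial size preserved.
#' @export
sppf_block <- function(x, out_channels, pool_kernel = 5L, params = NULL) {
  m <- new_sppf(dim(x)[1L], out_channels, k = pool_kernel)
  if (!is.null(params)) mod_load_state(m, params)
  feature_map(drop_batch(ft_array(mod_fwd(m, ft_from_array(unclass(x)),
                                          FALSE))))
}

#' Learnable-weight counts: ghost module vs dense convolution
#'
#' Counts convolution weights only (no biases, no normalization), the
#' quantity relevant to the efficiency claim of the ghost design: a ghost
#' module spends `c1*c2/r` weights on its primary 1x1 convolution and
#' `(r-1)*(c2/r)*k^2` on the cheap depthwise operations, against `c1*c2*k^2`
#' for the dense k x k convolution it replaces.
#'
#' @param cfg a [ghost_config()].
#' @return integer weight count.
#' @export
ghost_param_count <- function(cfg) {
  cp <- cfg$c2 %/% cfg$r
  as.integer(cfg$c1 * cp + (cfg$r - 1L) * cp * cfg$k^2)
}

#' @rdname ghost_param_count
#' @param c1,c2 input/output channels of the dense convolution.
#' @param k kernel size.
#' @export
dense_conv_param_count <- function(c1, c2, k = 3L) as.integer(c1 * c2 * k^2)
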