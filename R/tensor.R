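# Feature-map utilities.
#
# A feature map is a rank-3 numeric array (channels x height x width); the
# network internally carries a batch as rank-4 (C, H, W, N). The channel
# dimension is fastest-varying, so per-pixel channel vectors are contiguous.

#' Construct a feature map
#'
#' @param values numeric array with dim (channels, height, width).
#' @return the validated array, classed `feature_map`.
#' @export
feature_map <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L)
    stop("feature map must be a rank-3 array (C, H, W)")
  if (any(d < 1L)) stop("feature map dims must be >= 1")
  if (!all(is.finite(values))) stop("feature map entries must be finite")
  structure(values, class = "feature_map")
}

# Add a trailing batch dim of 1 if absent.
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  unclass(x)
}

drop_batch <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[4] == 1L)
  dim(x) <- d[1:3]
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Bilinear resize of a feature map or raster
#'
#' Half-pixel sample centers with edge clamping; the convention used for
#' image preprocessing and prototype-mask upsampling throughout the package.
#'
#' @param x array (C, H, W) or (C, H, W, N).
#' @param height,width output spatial size.
#' @return resized array with the same rank as the input.
#' @export
bilinear_resize <- function(x, height, width) {
  d3 <- length(dim(x)) == 3L
  xb <- as_batch(x)
  xd <- dim(xb)
  y <- cpp_bilinear_resize(xb, as.integer(xd), as.integer(height),
                           as.integer(width))
  dim(y) <- c(xd[1L], height, width, xd[4L])
  if (d3) drop_batch(y) else y
}

# Evaluate an expression under a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
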