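# Internal network-module framework.
#
# Feature maps travel between modules as float tensor handles ("ft"):
# external pointers to single-precision (C, H*W*N) matrices owned by the
# C++ side, with dims tracked alongside. A module is an environment holding
# leaf parameters (`par`), accumulated gradients (`gr`), non-learnable
# buffers (`buf`) and child modules (`sub`). `mod_fwd()` runs forward
# (caching what backward needs when `training = TRUE`); `mod_bwd()`
# consumes the cache, accumulates parameter gradients and returns the
# input-gradient handle. Backpropagation is hand-derived per module type;
# forward paths are pinned against naive loop oracles and backward paths
# against finite differences in the test suite.

ft_handle <- function(ptr, d) list(ptr = ptr, d = as.integer(d))

ft_from_array <- function(x) {
  xb <- as_batch(x)
  ft_handle(cpp_ft_new(xb, dim(xb)), dim(xb))
}

ft_array <- function(t) {
  y <- cpp_ft_get(t$ptr)
  y
}

conv_out_hw <- function(d, k, s, p) {
  c((d[2L] + 2L * p - k) %/% s + 1L, (d[3L] + 2L * p - k) %/% s + 1L)
}

new_mod <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$gr <- list()
  e$buf <- list()
  e$sub <- list()
  dots <- list(...)
  for (nm in names(dots)) assign(nm, dots[[nm]], envir = e)
  e
}

kaiming <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

ACT_CODES <- c(linear = 0L, silu = 1L, relu = 2L, sigmoid = 3L)

# ---- fused leaf: convolution + batch norm + activation ---------------------

new_cbs <- function(cin, cout, k = 1L, s = 1L, p = (k - 1L) %/% 2L,
                    act = "silu", norm = TRUE, bias = !norm,
                    eps = 1e-3, momentum = 0.03) {
  m <- new_mod("cbs", cin = as.integer(cin), cout = as.integer(cout),
               k = as.integer(k), s = as.integer(s), p = as.integer(p),
               bias = bias, bn = norm, actc = ACT_CODES[[act]],
               eps = eps, momentum = momentum)
  fan_in <- cin * k * k
  m$par$w <- matrix(kaiming(cout * fan_in, fan_in), cout, fan_in)
  if (bias) m$par$b <- numeric(cout)
  if (norm) {
    m$par$gamma <- rep(1, cout)
    m$par$beta <- rep(0, cout)
    m$buf$rmean <- rep(0, cout)
    m$buf$rvar <- rep(1, cout)
  }
  m
}

# Running-stat momentum: cumulative average for the first updates (so
# eval-mode inference is sane from the first epoch), decaying to the
# configured momentum.
bn_momentum <- function(m) {
  n <- m$bn_updates
  if (is.null(n)) n <- 0L
  max(m$momentum, 1 / (n + 1))
}

fwd_cbs <- function(m, x, training) {
  r <- cpp_cbs_fwd(x$ptr, m$par$w,
                   if (m$bias) m$par$b else numeric(0), m$bias,
                   m$cout, m$k, m$s, m$p, m$bn,
                   if (m$bn) m$par$gamma else numeric(0),
                   if (m$bn) m$par$beta else numeric(0),
                   if (m$bn) m$buf$rmean else numeric(0),
                   if (m$bn) m$buf$rvar else numeric(0),
                   m$eps, if (m$bn) bn_momentum(m) else 0, m$actc,
                   training)
  if (training) {
    m$cache <- list(x = x, cc = r$cache)
    if (m$bn) {
      m$buf$rmean <- r$rmean
      m$buf$rvar <- r$rvar
      m$bn_updates <- (if (is.null(m$bn_updates)) 0L else m$bn_updates) + 1L
    }
  }
  ft_handle(r$y, c(m$cout, conv_out_hw(x$d, m$k, m$s, m$p), x$d[4L]))
}

bwd_cbs <- function(m, gy) {
  ca <- m$cache
  r <- cpp_cbs_bwd(ca$x$ptr, ca$cc, gy$ptr, m$par$w, m$bias, m$cout,
                   m$k, m$s, m$p, m$bn,
                   if (m$bn) m$par$gamma else numeric(0), m$actc,
                   is.null(m$skip_gx))
  acc_grad(m, "w", r$gw)
  if (m$bias) acc_grad(m, "b", r$gb)
  if (m$bn) {
    acc_grad(m, "gamma", r$ggamma)
    acc_grad(m, "beta", r$gbeta)
  }
  ft_handle(r$gx, ca$x$d)
}

# ---- fused leaf: depthwise convolution + batch norm + activation ----------

new_dbs <- function(c, k = 3L, s = 1L, p = (k - 1L) %/% 2L, act = "silu",
                    norm = TRUE, eps = 1e-3, momentum = 0.03) {
  m <- new_mod("dbs", c = as.integer(c), k = as.integer(k),
               s = as.integer(s), p = as.integer(p), bn = norm,
               actc = ACT_CODES[[act]], eps = eps, momentum = momentum)
  m$par$w <- matrix(kaiming(c * k * k, k * k), c, k * k)
  if (norm) {
    m$par$gamma <- rep(1, c)
    m$par$beta <- rep(0, c)
    m$buf$rmean <- rep(0, c)
    m$buf$rvar <- rep(1, c)
  }
  m
}

fwd_dbs <- function(m, x, training) {
  r <- cpp_dbs_fwd(x$ptr, m$par$w, m$k, m$s, m$p, m$bn,
                   if (m$bn) m$par$gamma else numeric(0),
                   if (m$bn) m$par$beta else numeric(0),
                   if (m$bn) m$buf$rmean else numeric(0),
                   if (m$bn) m$buf$rvar else numeric(0),
                   m$eps, if (m$bn) bn_momentum(m) else 0, m$actc,
                   training)
  if (training) {
    m$cache <- list(x = x, cc = r$cache)
    if (m$bn) {
      m$buf$rmean <- r$rmean
      m$buf$rvar <- r$rvar
      m$bn_updates <- (if (is.null(m$bn_updates)) 0L else m$bn_updates) + 1L
    }
  }
  ft_handle(r$y, c(m$c, conv_out_hw(x$d, m$k, m$s, m$p), x$d[4L]))
}

bwd_dbs <- function(m, gy) {
  ca <- m$cache
  r <- cpp_dbs_bwd(ca$x$ptr, ca$cc, gy$ptr, m$par$w, m$k, m$s, m$p,
                   m$bn, if (m$bn) m$par$gamma else numeric(0), m$actc)
  acc_grad(m, "w", r$gw)
  if (m$bn) {
    acc_grad(m, "gamma", r$ggamma)
    acc_grad(m, "beta", r$gbeta)
  }
  ft_handle(r$gx, ca$x$d)
}

# ---- pooling / upsampling leaves ------------------------------------------

new_maxpool <- function(k = 5L) new_mod("maxpool", k = as.integer(k))

fwd_maxpool <- function(m, x, training) {
  r <- cpp_maxpool_fwd(x$ptr, m$k, training)
  if (training) m$cache <- list(amax = r$amax, d = x$d)
  ft_handle(r$y, x$d)
}

bwd_maxpool <- function(m, gy) {
  ft_handle(cpp_maxpool_bwd(gy$ptr, m$cache$amax), m$cache$d)
}

new_upsample2 <- function() new_mod("upsample2")

fwd_upsample2 <- function(m, x, training) {
  if (training) m$cache <- list(d = x$d)
  ft_handle(cpp_upsample2_fwd(x$ptr),
            c(x$d[1L], 2L * x$d[2L], 2L * x$d[3L], x$d[4L]))
}

bwd_upsample2 <- function(m, gy) {
  ft_handle(cpp_upsample2_bwd(gy$ptr), m$cache$d)
}

# ---- glue ------------------------------------------------------------------

ft_cat <- function(parts) {
  d <- parts[[1L]]$d
  cs <- sum(vapply(parts, function(p) p$d[1L], 0L))
  ft_handle(cpp_ft_cat(lapply(parts, `[[`, "ptr")), c(cs, d[2:4]))
}

ft_split <- function(x, sizes) {
  ptrs <- cpp_ft_split(x$ptr, as.integer(sizes))
  lapply(seq_along(sizes), function(i)
    ft_handle(ptrs[[i]], c(sizes[i], x$d[2:4])))
}

ft_add <- function(a, b) ft_handle(cpp_ft_add(a$ptr, b$ptr), a$d)
ft_mul <- function(a, b) ft_handle(cpp_ft_mul(a$ptr, b$ptr), a$d)

# ---- composites ------------------------------------------------------------

new_seq <- function(...) {
  m <- new_mod("seq")
  sub <- list(...)
  if (is.null(names(sub)))
    names(sub) <- paste0("s", seq_along(sub))
  m$sub <- sub
  m
}

fwd_seq <- function(m, x, training) {
  for (s in m$sub) x <- mod_fwd(s, x, training)
  x
}

bwd_seq <- function(m, gy) {
  for (s in rev(m$sub)) gy <- mod_bwd(s, gy)
  gy
}

# Channel gate shared by the squeeze-excitation layer (delta = ReLU) and
# the channel branch of the global attention module (delta = SiLU):
#   S = sigmoid(W2 . delta(W1 . GAP(x))), y = x * S per channel.
new_changate <- function(c, reduction = 4L, delta = "relu") {
  if (c %% reduction != 0L)
    stop("channels (", c, ") must be divisible by reduction (", reduction, ")")
  cr <- c %/% reduction
  m <- new_mod("changate", c = as.integer(c), cr = as.integer(cr),
               delta = delta)
  m$par$w1 <- matrix(kaiming(cr * c, c), cr, c)
  m$par$b1 <- numeric(cr)
  m$par$w2 <- matrix(kaiming(c * cr, cr), c, cr)
  m$par$b2 <- numeric(c)
  m
}

fwd_changate <- function(m, x, training) {
  gap <- cpp_ft_gap(x$ptr)
  z1 <- m$par$w1 %*% gap + m$par$b1
  a1 <- if (m$delta == "relu") pmax(z1, 0) else z1 * sigmoid(z1)
  s <- sigmoid(m$par$w2 %*% a1 + m$par$b2)
  y <- ft_handle(cpp_ft_scale_channels(x$ptr, s), x$d)
  if (training) m$cache <- list(x = x, gap = gap, z1 = z1, a1 = a1, s = s)
  y
}

bwd_changate <- function(m, gy) {
  ca <- m$cache
  hw <- prod(ca$x$d[2:3])
  gs <- cpp_ft_dot_channels(gy$ptr, ca$x$ptr)
  gx <- cpp_ft_scale_channels(gy$ptr, ca$s)
  gz2 <- gs * ca$s * (1 - ca$s)
  acc_grad(m, "w2", gz2 %*% t(ca$a1))
  acc_grad(m, "b2", rowSums(gz2))
  ga1 <- t(m$par$w2) %*% gz2
  gz1 <- if (m$delta == "relu") ga1 * (ca$z1 > 0) else {
    sg <- sigmoid(ca$z1)
    ga1 * sg * (1 + ca$z1 * (1 - sg))
  }
  acc_grad(m, "w1", gz1 %*% t(ca$gap))
  acc_grad(m, "b1", rowSums(gz1))
  ggap <- t(m$par$w1) %*% gz1
  ft_handle(cpp_ft_add_channels(gx, ggap / hw), ca$x$d)
}

# Ghost module: reduced primary 1x1 convolution plus cheap depthwise
# "ghost" features generated from it, concatenated to c2 channels.
new_ghost <- function(c1, c2, r = 2L, k = 3L, norm = TRUE, act = "silu") {
  if (c2 %% r != 0L) stop("c2 (", c2, ") must be divisible by r (", r, ")")
  cp <- c2 %/% r
  m <- new_mod("ghost", c1 = as.integer(c1), c2 = as.integer(c2),
               r = as.integer(r), cp = as.integer(cp))
  m$sub$primary <- new_cbs(c1, cp, k = 1L, act = act, norm = norm,
                           bias = FALSE)
  m$sub$cheap <- lapply(seq_len(r - 1L), function(i)
    new_dbs(cp, k = k, s = 1L, act = act, norm = norm))
  m
}

fwd_ghost <- function(m, x, training) {
  x1 <- mod_fwd(m$sub$primary, x, training)
  parts <- c(list(x1), lapply(m$sub$cheap, function(ch)
    mod_fwd(ch, x1, training)))
  ft_cat(parts)
}

bwd_ghost <- function(m, gy) {
  r <- length(m$sub$cheap) + 1L
  chunks <- ft_split(gy, rep(m$cp, r))
  g1 <- chunks[[1L]]
  for (i in seq_along(m$sub$cheap))
    g1 <- ft_add(g1, mod_bwd(m$sub$cheap[[i]], chunks[[i + 1L]]))
  mod_bwd(m$sub$primary, g1)
}

# Ghost bottleneck: ghost module -> (stride-2 depthwise) -> (SE gate) ->
# ghost module, summed with an identity or depthwise+1x1 shortcut.
new_gbneck <- function(c1, c2, r = 2L, k = 3L, s = 1L, use_se = FALSE,
                       se_reduction = 4L) {
  if (!s %in% c(1L, 2L)) stop("stride must be 1 or 2, got ", s)
  m <- new_mod("gbneck", c1 = as.integer(c1), c2 = as.integer(c2),
               s = as.integer(s), use_se = use_se)
  m$sub$g1 <- new_ghost(c1, c2, r = r, k = k)
  if (s == 2L) m$sub$down <- new_dbs(c2, k = k, s = 2L, act = "linear")
  if (use_se) m$sub$se <- new_changate(c2, se_reduction, delta = "relu")
  m$sub$g2 <- new_ghost(c2, c2, r = r, k = k)
  m$identity <- (s == 1L && c1 == c2)
  if (!m$identity) {
    m$sub$short_dw <- new_dbs(c1, k = k, s = s, act = "linear")
    m$sub$short_pw <- new_cbs(c1, c2, k = 1L, act = "linear")
  }
  m
}

fwd_gbneck <- function(m, x, training) {
  h <- mod_fwd(m$sub$g1, x, training)
  if (m$s == 2L) h <- mod_fwd(m$sub$down, h, training)
  if (m$use_se) h <- mod_fwd(m$sub$se, h, training)
  h <- mod_fwd(m$sub$g2, h, training)
  sc <- if (m$identity) x else
    mod_fwd(m$sub$short_pw, mod_fwd(m$sub$short_dw, x, training), training)
  ft_add(h, sc)
}

bwd_gbneck <- function(m, gy) {
  g <- mod_bwd(m$sub$g2, gy)
  if (m$use_se) g <- mod_bwd(m$sub$se, g)
  if (m$s == 2L) g <- mod_bwd(m$sub$down, g)
  gx <- mod_bwd(m$sub$g1, g)
  gsc <- if (m$identity) gy else
    mod_bwd(m$sub$short_dw, mod_bwd(m$sub$short_pw, gy))
  ft_add(gx, gsc)
}

# Global attention module: channel gate (SiLU mlp) then spatial gate (two
# k x k convolutions with channel reduction/restoration, sigmoid), each
# multiplied into the map.
new_gam <- function(c, reduction = 4L, spatial_kernel = 7L) {
  if (spatial_kernel %% 2L == 0L) stop("spatial kernel must be odd")
  m <- new_mod("gam", c = as.integer(c))
  m$sub$chan <- new_changate(c, reduction, delta = "silu")
  cr <- c %/% reduction
  m$sub$sp1 <- new_cbs(c, cr, k = spatial_kernel, act = "silu", norm = TRUE)
  m$sub$sp2 <- new_cbs(cr, c, k = spatial_kernel, act = "sigmoid",
                       norm = FALSE, bias = TRUE)
  m
}

fwd_gam <- function(m, x, training) {
  xc <- mod_fwd(m$sub$chan, x, training)
  as_map <- mod_fwd(m$sub$sp2, mod_fwd(m$sub$sp1, xc, training), training)
  if (training) m$cache <- list(xc = xc, as_map = as_map)
  ft_mul(xc, as_map)
}

bwd_gam <- function(m, gy) {
  ca <- m$cache
  gxc <- ft_mul(gy, ca$as_map)
  gas <- ft_mul(gy, ca$xc)
  gxc <- ft_add(gxc, mod_bwd(m$sub$sp1, mod_bwd(m$sub$sp2, gas)))
  mod_bwd(m$sub$chan, gxc)
}

# C2f inner bottleneck: two 3x3 convolutions with optional residual.
new_bneck <- function(c, shortcut = TRUE) {
  m <- new_mod("bneck", shortcut = shortcut)
  m$sub$cv1 <- new_cbs(c, c, k = 3L)
  m$sub$cv2 <- new_cbs(c, c, k = 3L)
  m
}

fwd_bneck <- function(m, x, training) {
  y <- mod_fwd(m$sub$cv2, mod_fwd(m$sub$cv1, x, training), training)
  if (m$shortcut) ft_add(y, x) else y
}

bwd_bneck <- function(m, gy) {
  gx <- mod_bwd(m$sub$cv1, mod_bwd(m$sub$cv2, gy))
  if (m$shortcut) ft_add(gx, gy) else gx
}

# Cross-stage-partial block with 2 convolutions (faster).
new_c2f <- function(cin, cout, n = 1L, shortcut = TRUE) {
  ch <- cout %/% 2L
  m <- new_mod("c2f", ch = as.integer(ch), n = as.integer(n))
  m$sub$cv1 <- new_cbs(cin, 2L * ch, k = 1L)
  m$sub$blocks <- lapply(seq_len(n), function(i) new_bneck(ch, shortcut))
  m$sub$cv2 <- new_cbs((2L + n) * ch, cout, k = 1L)
  m
}

fwd_c2f <- function(m, x, training) {
  y0 <- mod_fwd(m$sub$cv1, x, training)
  parts <- ft_split(y0, c(m$ch, m$ch))
  cur <- parts[[2L]]
  for (b in m$sub$blocks) {
    cur <- mod_fwd(b, cur, training)
    parts <- c(parts, list(cur))
  }
  mod_fwd(m$sub$cv2, ft_cat(parts), training)
}

bwd_c2f <- function(m, gy) {
  g <- mod_bwd(m$sub$cv2, gy)
  chunks <- ft_split(g, rep(m$ch, 2L + m$n))
  gcur <- chunks[[2L + m$n]]
  for (i in rev(seq_len(m$n))) {
    gprev <- mod_bwd(m$sub$blocks[[i]], gcur)
    gcur <- if (i > 1L) ft_add(chunks[[1L + i]], gprev) else gprev
  }
  gb <- ft_add(chunks[[2L]], gcur)
  mod_bwd(m$sub$cv1, ft_cat(list(chunks[[1L]], gb)))
}

# Spatial pyramid pooling (fast).
new_sppf <- function(cin, cout, k = 5L) {
  ch <- cin %/% 2L
  m <- new_mod("sppf", ch = as.integer(ch))
  m$sub$cv1 <- new_cbs(cin, ch, k = 1L)
  m$sub$mp <- lapply(1:3, function(i) new_maxpool(k))
  m$sub$cv2 <- new_cbs(4L * ch, cout, k = 1L)
  m
}

fwd_sppf <- function(m, x, training) {
  y1 <- mod_fwd(m$sub$cv1, x, training)
  p1 <- mod_fwd(m$sub$mp[[1L]], y1, training)
  p2 <- mod_fwd(m$sub$mp[[2L]], p1, training)
  p3 <- mod_fwd(m$sub$mp[[3L]], p2, training)
  mod_fwd(m$sub$cv2, ft_cat(list(y1, p1, p2, p3)), training)
}

bwd_sppf <- function(m, gy) {
  g <- mod_bwd(m$sub$cv2, gy)
  ch <- ft_split(g, rep(m$ch, 4L))
  g3 <- mod_bwd(m$sub$mp[[3L]], ch[[4L]])
  g2 <- mod_bwd(m$sub$mp[[2L]], ft_add(ch[[3L]], g3))
  g1 <- mod_bwd(m$sub$mp[[1L]], ft_add(ch[[2L]], g2))
  mod_bwd(m$sub$cv1, ft_add(ch[[1L]], g1))
}

# ---- dispatch --------------------------------------------------------------

mod_fwd <- function(m, x, training = FALSE) {
  switch(m$type,
    cbs = fwd_cbs(m, x, training),
    dbs = fwd_dbs(m, x, training),
    maxpool = fwd_maxpool(m, x, training),
    upsample2 = fwd_upsample2(m, x, training),
    seq = fwd_seq(m, x, training),
    changate = fwd_changate(m, x, training),
    ghost = fwd_ghost(m, x, training),
    gbneck = fwd_gbneck(m, x, training),
    gam = fwd_gam(m, x, training),
    bneck = fwd_bneck(m, x, training),
    c2f = fwd_c2f(m, x, training),
    sppf = fwd_sppf(m, x, training),
    stop("unknown module type: ", m$type))
}

mod_bwd <- function(m, gy) {
  switch(m$type,
    cbs = bwd_cbs(m, gy),
    dbs = bwd_dbs(m, gy),
    maxpool = bwd_maxpool(m, gy),
    upsample2 = bwd_upsample2(m, gy),
    seq = bwd_seq(m, gy),
    changate = bwd_changate(m, gy),
    ghost = bwd_ghost(m, gy),
    gbneck = bwd_gbneck(m, gy),
    gam = bwd_gam(m, gy),
    bneck = bwd_bneck(m, gy),
    c2f = bwd_c2f(m, gy),
    sppf = bwd_sppf(m, gy),
    stop("unknown module type: ", m$type))
}

# Drop per-batch caches (after a step, or before serializing).
mod_clear_cache <- function(m) {
  walk <- function(x) {
    if (!is.null(x$cache)) x$cache <- NULL
    for (s in x$sub) {
      if (is.environment(s)) walk(s) else for (ss in s) walk(ss)
    }
  }
  walk(m)
  invisible(NULL)
}

# ---- parameter bookkeeping -------------------------------------------------

acc_grad <- function(m, name, g) {
  cur <- m$gr[[name]]
  g <- as.vector(g)
  m$gr[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# All leaf modules (those holding parameters), depth-first.
mod_leaves <- function(m) {
  out <- list()
  walk <- function(x) {
    if (length(x$par) || length(x$buf)) out[[length(out) + 1L]] <<- x
    for (s in x$sub) {
      if (is.environment(s)) walk(s)
      else for (ss in s) walk(ss)
    }
  }
  walk(m)
  out
}

mod_zero_grads <- function(m) {
  for (lf in mod_leaves(m)) lf$gr <- list()
  invisible(NULL)
}

# Flat named parameter archive: learnable parameters and batch-norm running
# statistics, hierarchical dotted names.
mod_state <- function(m, prefix = "") {
  out <- list()
  walk <- function(x, pre) {
    for (nm in names(x$par)) out[[paste0(pre, nm)]] <<- x$par[[nm]]
    for (nm in names(x$buf)) out[[paste0(pre, nm)]] <<- x$buf[[nm]]
    for (snm in names(x$sub)) {
      s <- x$sub[[snm]]
      if (is.environment(s)) walk(s, paste0(pre, snm, "."))
      else for (i in seq_along(s))
        walk(s[[i]], paste0(pre, snm, i, "."))
    }
  }
  walk(m, prefix)
  out
}

mod_load_state <- function(m, state, prefix = "") {
  walk <- function(x, pre) {
    for (nm in names(x$par)) {
      key <- paste0(pre, nm)
      if (!is.null(state[[key]])) {
        v <- state[[key]]
        stopifnot(length(v) == length(x$par[[nm]]))
        dim(v) <- dim(x$par[[nm]])
        x$par[[nm]] <- v
      }
    }
    for (nm in names(x$buf)) {
      key <- paste0(pre, nm)
      if (!is.null(state[[key]])) x$buf[[nm]] <- as.vector(state[[key]])
    }
    for (snm in names(x$sub)) {
      s <- x$sub[[snm]]
      if (is.environment(s)) walk(s, paste0(pre, snm, "."))
      else for (i in seq_along(s))
        walk(s[[i]], paste0(pre, snm, i, "."))
    }
  }
  walk(m, prefix)
  invisible(m)
}

# Count of learnable parameters (running statistics excluded).
mod_n_params <- function(m) {
  sum(vapply(mod_leaves(m), function(lf)
    sum(vapply(lf$par, length, 0L)), 0))
}

# Convolution-weight count only (the quantity compared in the ghost-vs-dense
# efficiency checks, which disable normalization).
mod_n_conv_weights <- function(m) {
  sum(vapply(mod_leaves(m), function(lf) {
    if (lf$type %in% c("cbs", "dbs")) length(lf$par$w) else 0L
  }, 0))
}

# Zero every learnable parameter (used by analytic gate tests).
mod_zero_params <- function(m) {
  for (lf in mod_leaves(m))
    for (nm in names(lf$par))
      lf$par[[nm]][] <- 0
  invisible(m)
}
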