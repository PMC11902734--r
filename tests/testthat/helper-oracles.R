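# Naive loop-based reference implementations of every network block,
# written independently of the package internals. They consume the flat
# parameter lists produced by block_init() / model_state().
#
# Weight layout (documented contract): dense convolution weights are
# (cout, cin*k*k) matrices with column index c + cin*(dh + k*dw) + 1 for
# 0-based kernel offset (dh, dw); depthwise weights are (C, k*k) with
# column dh + k*dw + 1.

o_conv <- function(x, w, k, s, p, bias = NULL) {
  d <- dim(x)
  cin <- d[1]; h <- d[2]; wd <- d[3]
  cout <- nrow(w)
  ho <- (h + 2 * p - k) %/% s + 1
  wo <- (wd + 2 * p - k) %/% s + 1
  y <- array(0, c(cout, ho, wo))
  for (co in 1:cout) for (j in 1:wo) for (i in 1:ho) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (dw in 0:(k - 1)) for (dh in 0:(k - 1)) {
      hi <- (i - 1) * s - p + dh + 1
      wi <- (j - 1) * s - p + dw + 1
      if (hi >= 1 && hi <= h && wi >= 1 && wi <= wd)
        for (c in 1:cin)
          acc <- acc + x[c, hi, wi] * w[co, c + cin * (dh + k * dw)]
    }
    y[co, i, j] <- acc
  }
  y
}

o_dw <- function(x, w, k, s, p) {
  d <- dim(x)
  cc <- d[1]; h <- d[2]; wd <- d[3]
  ho <- (h + 2 * p - k) %/% s + 1
  wo <- (wd + 2 * p - k) %/% s + 1
  y <- array(0, c(cc, ho, wo))
  for (c in 1:cc) for (j in 1:wo) for (i in 1:ho) {
    acc <- 0
    for (dw in 0:(k - 1)) for (dh in 0:(k - 1)) {
      hi <- (i - 1) * s - p + dh + 1
      wi <- (j - 1) * s - p + dw + 1
      if (hi >= 1 && hi <= h && wi >= 1 && wi <= wd)
        acc <- acc + x[c, hi, wi] * w[c, 1 + dh + k * dw]
    }
    y[c, i, j] <- acc
  }
  y
}

o_bn_eval <- function(x, gamma, beta, rmean, rvar, eps = 1e-3) {
  y <- x
  for (c in seq_len(dim(x)[1]))
    y[c, , ] <- gamma[c] * (x[c, , ] - rmean[c]) / sqrt(rvar[c] + eps) +
      beta[c]
  y
}

o_sigmoid <- function(x) 1 / (1 + exp(-x))

o_act <- function(x, kind) {
  switch(kind,
    linear = x,
    silu = x * o_sigmoid(x),
    relu = pmax(x, 0),
    sigmoid = o_sigmoid(x))
}

# conv + optional batch norm (inference statistics) + activation
o_cbs <- function(x, p, pre, cout, k = 1, s = 1, pd = (k - 1) %/% 2,
                  act = "silu", norm = TRUE, bias = FALSE) {
  y <- o_conv(x, p[[paste0(pre, "w")]], k, s, pd,
              bias = if (bias) p[[paste0(pre, "b")]] else NULL)
  if (norm)
    y <- o_bn_eval(y, p[[paste0(pre, "gamma")]], p[[paste0(pre, "beta")]],
                   p[[paste0(pre, "rmean")]], p[[paste0(pre, "rvar")]])
  o_act(y, act)
}

o_dbs <- function(x, p, pre, k = 3, s = 1, act = "silu", norm = TRUE) {
  y <- o_dw(x, p[[paste0(pre, "w")]], k, s, (k - 1) %/% 2)
  if (norm)
    y <- o_bn_eval(y, p[[paste0(pre, "gamma")]], p[[paste0(pre, "beta")]],
                   p[[paste0(pre, "rmean")]], p[[paste0(pre, "rvar")]])
  o_act(y, act)
}

o_cat <- function(parts) {
  d <- dim(parts[[1]])
  cs <- vapply(parts, function(q) dim(q)[1], 0L)
  y <- array(0, c(sum(cs), d[2], d[3]))
  off <- 0
  for (q in parts) {
    y[off + seq_len(dim(q)[1]), , ] <- q
    off <- off + dim(q)[1]
  }
  y
}

o_ghost <- function(x, cfg, p, pre = "") {
  cp <- cfg$c2 %/% cfg$r
  x1 <- o_cbs(x, p, paste0(pre, "primary."), cp, k = 1,
              act = cfg$act, norm = cfg$norm)
  parts <- list(x1)
  for (i in seq_len(cfg$r - 1))
    parts <- c(parts, list(o_dbs(x1, p, paste0(pre, "cheap", i, "."),
                                 k = cfg$k, act = cfg$act,
                                 norm = cfg$norm)))
  o_cat(parts)
}

o_changate <- function(x, p, pre = "", delta = "relu") {
  d <- dim(x)
  gap <- apply(x, 1, mean)
  z1 <- as.vector(p[[paste0(pre, "w1")]] %*% gap + p[[paste0(pre, "b1")]])
  a1 <- if (delta == "relu") pmax(z1, 0) else z1 * o_sigmoid(z1)
  s <- o_sigmoid(as.vector(p[[paste0(pre, "w2")]] %*% a1 +
                             p[[paste0(pre, "b2")]]))
  y <- x
  for (c in seq_len(d[1])) y[c, , ] <- x[c, , ] * s[c]
  y
}

o_gbneck <- function(x, cfg, p) {
  gcfg1 <- list(c1 = cfg$c1, c2 = cfg$c2, r = cfg$r, k = cfg$k,
                norm = TRUE, act = "silu")
  h <- o_ghost(x, gcfg1, p, "g1.")
  if (cfg$s == 2) h <- o_dbs(h, p, "down.", k = cfg$k, s = 2, act = "linear")
  if (cfg$use_se) h <- o_changate(h, p, "se.", delta = "relu")
  gcfg2 <- list(c1 = cfg$c2, c2 = cfg$c2, r = cfg$r, k = cfg$k,
                norm = TRUE, act = "silu")
  h <- o_ghost(h, gcfg2, p, "g2.")
  sc <- if (cfg$s == 1 && cfg$c1 == cfg$c2) x else {
    tmp <- o_dbs(x, p, "short_dw.", k = cfg$k, s = cfg$s, act = "linear")
    o_cbs(tmp, p, "short_pw.", cfg$c2, k = 1, act = "linear")
  }
  h + sc
}

o_gam <- function(x, cfg, p) {
  xc <- o_changate(x, p, "chan.", delta = "silu")
  cr <- cfg$channels %/% cfg$reduction
  a <- o_cbs(xc, p, "sp1.", cr, k = cfg$spatial_kernel, act = "silu",
             norm = TRUE)
  as_map <- o_cbs(a, p, "sp2.", cfg$channels, k = cfg$spatial_kernel,
                  act = "sigmoid", norm = FALSE, bias = TRUE)
  xc * as_map
}

o_bneck <- function(x, p, pre, shortcut = TRUE) {
  cc <- dim(x)[1]
  y <- o_cbs(x, p, paste0(pre, "cv1."), cc, k = 3)
  y <- o_cbs(y, p, paste0(pre, "cv2."), cc, k = 3)
  if (shortcut) y + x else y
}

o_c2f <- function(x, p, cout, n, shortcut = TRUE) {
  ch <- cout %/% 2
  y0 <- o_cbs(x, p, "cv1.", 2 * ch, k = 1)
  a <- y0[seq_len(ch), , , drop = FALSE]
  b <- y0[ch + seq_len(ch), , , drop = FALSE]
  parts <- list(a, b)
  cur <- b
  for (i in seq_len(n)) {
    cur <- o_bneck(cur, p, paste0("blocks", i, "."), shortcut)
    parts <- c(parts, list(cur))
  }
  o_cbs(o_cat(parts), p, "cv2.", cout, k = 1)
}

o_maxpool <- function(x, k) {
  d <- dim(x)
  p <- (k - 1) %/% 2
  y <- x
  for (c in seq_len(d[1])) for (j in seq_len(d[3])) for (i in seq_len(d[2])) {
    hs <- max(1, i - p):min(d[2], i + p)
    ws <- max(1, j - p):min(d[3], j + p)
    y[c, i, j] <- max(x[c, hs, ws])
  }
  y
}

o_sppf <- function(x, p, cout, k = 5) {
  ch <- dim(x)[1] %/% 2
  y1 <- o_cbs(x, p, "cv1.", ch, k = 1)
  p1 <- o_maxpool(y1, k)
  p2 <- o_maxpool(p1, k)
  p3 <- o_maxpool(p2, k)
  o_cbs(o_cat(list(y1, p1, p2, p3)), p, "cv2.", cout, k = 1)
}

# Maximum elementwise deviation relative to the oracle's largest magnitude.
rel_err <- function(got, want) {
  max(abs(got - want)) / max(max(abs(want)), 1e-6)
}

# Random feature map with approximately unit-scale entries.
rand_fm <- function(c, h, w) feature_map(array(rnorm(c * h * w), c(c, h, w)))
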