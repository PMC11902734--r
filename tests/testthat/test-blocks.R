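# Block-level behaviour: shape contracts, analytic gate values, parameter
# counts, and agreement with naive loop oracles on random instances.

test_that("ghost module matches contract and oracle", {
  set.seed(11)
  cfg <- ghost_config(c1 = 6, c2 = 8, r = 2, k = 3)
  p <- block_init("ghost", cfg)
  x <- rand_fm(6, 7, 5)
  y <- ghost_module(x, cfg, p)
  expect_equal(dim(y), c(8L, 7L, 5L))
  expect_lt(rel_err(unclass(y), o_ghost(unclass(x), cfg, p)), 1e-5)

  # identity construction: primary = identity 1x1, cheap = centered delta,
  # no normalization/activation -> output = concat(x, x)
  cfg2 <- ghost_config(c1 = 4, c2 = 8, r = 2, k = 3, norm = FALSE,
                       act = "linear")
  p2 <- block_init("ghost", cfg2)
  p2[["primary.w"]] <- diag(4)
  w <- matrix(0, 4, 9)
  w[, 1 + 1 + 3 * 1] <- 1     # kernel offset (1, 1) = center
  p2[["cheap1.w"]] <- w
  x2 <- rand_fm(4, 5, 6)
  y2 <- ghost_module(x2, cfg2, p2)
  expect_equal(unclass(y2)[1:4, , ], unclass(x2), tolerance = 1e-6)
  expect_equal(unclass(y2)[5:8, , ], unclass(x2), tolerance = 1e-6)
})

test_that("ghost weight counts beat dense convolutions", {
  cfg <- ghost_config(c1 = 16, c2 = 32, r = 2, k = 3)
  expect_identical(ghost_param_count(cfg), 400L)
  expect_identical(dense_conv_param_count(16, 32, 3), 4608L)
  # counting weights of a built module (norm off) agrees with the formula
  m <- orchardseg:::build_block("ghost",
    ghost_config(16, 32, norm = FALSE, act = "linear"))
  expect_identical(orchardseg:::mod_n_conv_weights(m), 400)
})

test_that("squeeze-excitation layer: analytic cases and oracle", {
  cfg <- se_config(channels = 8, reduction = 4)
  # all-zero parameters -> gate sigmoid(0) = 0.5 for every channel
  p0 <- lapply(block_init("se", cfg), function(v) v * 0)
  x <- rand_fm(8, 4, 4)
  expect_equal(unclass(se_layer(x, cfg, p0)), unclass(x) * 0.5,
               tolerance = 1e-6)
  # constant channel -> its pooled value equals the constant (gate varies
  # smoothly in it); checked through the oracle path
  set.seed(12)
  p <- block_init("se", cfg)
  y <- se_layer(x, cfg, p)
  expect_lt(rel_err(unclass(y), o_changate(unclass(x), p)), 1e-5)
  # gates lie strictly inside (0, 1): output strictly smaller in magnitude
  expect_true(all(abs(y) < abs(unclass(x)) + 1e-12))
})

test_that("ghost bottleneck: residual identity, stride, oracle", {
  # zeroed main path with identity shortcut reproduces the input exactly
  cfg1 <- ghost_config(c1 = 8, c2 = 8, s = 1)
  p1 <- block_init("ghost_bottleneck", cfg1)
  for (nm in names(p1))
    if (!grepl("rvar", nm)) p1[[nm]] <- p1[[nm]] * 0
  x <- rand_fm(8, 6, 6)
  expect_equal(unclass(ghost_bottleneck(x, cfg1, p1)), unclass(x),
               tolerance = 1e-6)

  # stride 2 halves spatial dims
  cfg2 <- ghost_config(c1 = 8, c2 = 12, s = 2, use_se = TRUE)
  set.seed(13)
  p2 <- block_init("ghost_bottleneck", cfg2)
  x2 <- rand_fm(8, 10, 10)
  y2 <- ghost_bottleneck(x2, cfg2, p2)
  expect_equal(dim(y2), c(12L, 5L, 5L))
  expect_lt(rel_err(unclass(y2), o_gbneck(unclass(x2), cfg2, p2)), 1e-5)

  expect_error(ghost_config(8, 12, s = 3), "stride")
})

test_that("global attention module: analytic case, bound, oracle", {
  cfg <- gam_config(channels = 8, reduction = 4, spatial_kernel = 3)
  # all-zero parameters: both gates are sigmoid(0) = 0.5 -> 0.25 * x
  p0 <- lapply(block_init("gam", cfg), function(v) v * 0)
  x <- rand_fm(8, 5, 5)
  expect_equal(unclass(gam(x, cfg, p0)), unclass(x) * 0.25,
               tolerance = 1e-6)
  # attention factors in (0, 1): output never exceeds input in magnitude
  set.seed(14)
  p <- block_init("gam", cfg)
  y <- gam(x, cfg, p)
  expect_true(all(abs(y) <= abs(unclass(x)) + 1e-12))
  expect_lt(rel_err(unclass(y), o_gam(unclass(x), cfg, p)), 1e-5)
})

test_that("attention blocks are not positively homogeneous", {
  # doubling the input does not double the output (the gates saturate),
  # guarding against an accidental linear implementation
  set.seed(15)
  cfg <- se_config(8, 4)
  p <- block_init("se", cfg)
  x <- rand_fm(8, 4, 4)
  y1 <- unclass(se_layer(x, cfg, p))
  y2 <- unclass(se_layer(feature_map(unclass(x) * 2), cfg, p))
  expect_gt(max(abs(y2 - 2 * y1)), 1e-4)
  gcfg <- gam_config(8, 4, 3)
  gp <- block_init("gam", gcfg)
  g1 <- unclass(gam(x, gcfg, gp))
  g2 <- unclass(gam(feature_map(unclass(x) * 2), gcfg, gp))
  expect_gt(max(abs(g2 - 2 * g1)), 1e-4)
})

test_that("conv block geometry and oracle", {
  set.seed(16)
  x <- rand_fm(3, 8, 8)
  y <- conv_block(x, 6, kernel = 3, stride = 2, padding = 1)
  expect_equal(dim(y), c(6L, 4L, 4L))
  # 640 -> 320 halving is the same arithmetic at any size:
  expect_equal((640 + 2 * 1 - 3) %/% 2 + 1, 320)
  m <- orchardseg:::new_cbs(3L, 5L, k = 3L, s = 1L)
  p <- orchardseg:::mod_state(m)
  y2 <- conv_block(x, 5, kernel = 3, params = p)
  expect_lt(rel_err(unclass(y2), o_cbs(unclass(x), p, "", 5, k = 3)), 1e-5)
  expect_error(conv_block(x, 4, kernel = 11, padding = 0), "kernel")
})

test_that("c2f block matches the compositional oracle", {
  set.seed(17)
  for (n in c(1L, 2L)) {
    m <- orchardseg:::new_c2f(6L, 8L, n = n)
    p <- orchardseg:::mod_state(m)
    x <- rand_fm(6, 6, 6)
    y <- c2f_block(x, 8, n_iterations = n, params = p)
    expect_equal(dim(y), c(8L, 6L, 6L))
    expect_lt(rel_err(unclass(y), o_c2f(unclass(x), p, 8, n)), 1e-5)
  }
  expect_error(c2f_block(rand_fm(4, 4, 4), 8, n_iterations = 0L))
})

test_that("sppf block: pooling identities and oracle", {
  set.seed(18)
  m <- orchardseg:::new_sppf(8L, 10L, k = 5L)
  p <- orchardseg:::mod_state(m)
  x <- rand_fm(8, 9, 9)
  y <- sppf_block(x, 10, pool_kernel = 5, params = p)
  expect_equal(dim(y), c(10L, 9L, 9L))
  expect_lt(rel_err(unclass(y), o_sppf(unclass(x), p, 10)), 1e-5)
  # chained 5x5 stride-1 max pools equal single 9x9 and 13x13 pools
  z <- unclass(rand_fm(2, 12, 12))
  p1 <- o_maxpool(z, 5)
  expect_equal(o_maxpool(p1, 5), o_maxpool(z, 9))
  expect_equal(o_maxpool(o_maxpool(p1, 5), 5), o_maxpool(z, 13))
})

test_that("blocks preserve finiteness and shapes on random inputs", {
  set.seed(19)
  for (i in 1:5) {
    cfg <- ghost_config(c1 = 4, c2 = 8, s = sample(1:2, 1),
                        use_se = runif(1) < 0.5)
    x <- rand_fm(4, 8, 8)
    y <- ghost_bottleneck(x, cfg)
    expect_true(all(is.finite(y)))
    expect_equal(dim(y)[1], 8L)
    expect_equal(dim(y)[2], if (cfg$s == 2) 4L else 8L)
  }
})
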