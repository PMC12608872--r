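test_that("partial convolution honours the passthrough contract and degenerate ratio", {
  set.seed(11)
  x <- rand_fm(8, 8, 16)
  spec <- pconv_spec(16, c_p = 4)
  w <- sealscope:::init_pconv_weights(spec)
  y <- pconv_forward(x, spec, w)
  expect_identical(y[, , 5:16], x[, , 5:16])           # untouched channels
  expect_equal(dim(y), dim(x))

  # r = 1: identical to a dense convolution with the same weights
  spec1 <- pconv_spec(16, c_p = 16)
  w1 <- sealscope:::init_pconv_weights(spec1)
  expect_identical(pconv_forward(x, spec1, w1), conv2d(x, w1$w))

  expect_error(pconv_spec(16, c_p = 20), "c_p")
  expect_error(pconv_spec(16, k = 4), "odd")
})

test_that("the processed slice of a partial convolution matches the summation oracle", {
  set.seed(12)
  x <- rand_fm(6, 6, 8)
  spec <- pconv_spec(8, c_p = 2, k = 3)
  w <- sealscope:::init_pconv_weights(spec)
  y <- pconv_forward(x, spec, w)
  ref <- oracle_conv2d(x[, , 1:2, drop = FALSE], w$w)
  expect_lt(max(abs(y[, , 1:2] - ref)), 1e-10)
})

test_that("memory-access accounting reproduces the dominant-term ratios", {
  m <- pconv_memory_access(10, 10, 64, 16, 3)
  expect_equal(m$ratio, 0.25)
  expect_equal(m$pconv_cost, 10 * 10 * 2 * 16 + 9 * 16^2)
  expect_equal(m$standard_cost, 10 * 10 * 2 * 64 + 9 * 64^2)
  expect_equal(pconv_memory_access(5, 5, 32, 32)$ratio, 1.0)
})

test_that("FasterNet block is a residual unit with the documented composition", {
  set.seed(13)
  spec <- fasternet_spec(8)
  w <- sealscope:::init_fasternet_weights(spec)

  # zero projection weights -> pure identity
  w0 <- w; w0$w2[] <- 0
  x <- rand_fm(8, 8, 8)
  expect_equal(fasternet_block(x, spec, w0), x)

  # shape contract at other sizes
  spec32 <- fasternet_spec(32)
  w32 <- sealscope:::init_fasternet_weights(spec32)
  expect_equal(dim(fasternet_block(rand_fm(8, 8, 32), spec32, w32)), c(8, 8, 32))

  # equals an independent composition of the five primitive steps
  x <- rand_fm(4, 4, 8)
  h <- x
  h[, , 1:2] <- oracle_conv2d(x[, , 1:2, drop = FALSE], w$pconv$w)  # PConv
  h <- oracle_conv2d(h, w$w1)                                       # PWConv 1
  h <- sweep(sweep(h, 3, w$g1, `*`), 3, w$b1, `+`)                  # norm
  h <- gelu(h)                                                      # act
  h <- oracle_conv2d(h, w$w2)                                       # PWConv 2
  expect_lt(max(abs(fasternet_block(x, spec, w) - (x + h))), 1e-8)
})

test_that("C2f-Faster keeps shape, handles n = 0, and is lighter than C2f", {
  set.seed(14)
  spec <- c2f_faster_spec(64, 64, n = 1)
  w <- sealscope:::init_c2f_faster_weights(spec)
  expect_equal(dim(c2f_faster(rand_fm(16, 16, 64), spec, w)), c(16, 16, 64))

  spec0 <- c2f_faster_spec(32, 32, n = 0)
  w0 <- sealscope:::init_c2f_faster_weights(spec0)
  expect_equal(dim(c2f_faster(rand_fm(6, 6, 32), spec0, w0)), c(6, 6, 32))

  # strictly fewer learnable scalars than the standard-bottleneck stage
  n_fast <- block_params(c2f_faster_spec(64, 64, 1))
  n_std <- sealscope:::cnt_c2f(64, 64, 1, "deploy")
  expect_lt(n_fast, n_std)
})

test_that("hierarchical contextualization builds the documented pyramid", {
  set.seed(15)
  cfg <- focal_config(8, L = 3, kernels = c(3, 5, 7))
  w <- sealscope:::init_focal_weights(cfg)
  x <- rand_fm(6, 6, 8)
  lv <- hierarchical_contextualize(x, cfg, w)
  expect_length(lv, 4)

  # global level equals the arithmetic mean of Z^(L), by direct summation
  zl <- lv[[3]]
  man <- apply(zl, 3, function(m) sum(m) / length(m))
  expect_lt(max(abs(sweep(lv[[4]], 3, man, `-`))), 1e-10)

  # L = 0: single level, the per-channel mean of Z^(0) everywhere
  cfg0 <- focal_config(8, L = 0, kernels = integer(0))
  w0 <- sealscope:::init_focal_weights(cfg0)
  lv0 <- hierarchical_contextualize(x, cfg0, w0)
  expect_length(lv0, 1)
  z0 <- oracle_conv2d(x, w0$fz$w, w0$fz$b)
  expect_lt(max(abs(lv0[[1]] - array(rep(apply(z0, 3, mean), each = 36), dim(x)))), 1e-10)

  expect_error(focal_config(8, L = -1), "focal_levels")
})

test_that("gated aggregation matches the elementwise summation oracle", {
  set.seed(16)
  levels <- lapply(1:3, function(i) rand_fm(4, 4, 8))
  gates <- rand_fm(4, 4, 3)
  expect_lt(max(abs(gated_aggregation(levels, gates) -
                      oracle_gated_agg(levels, gates))), 1e-12)

  # identity and selector cases
  one <- array(1, c(4, 4, 1))
  expect_equal(gated_aggregation(levels[1], one), levels[[1]])
  sel <- array(0, c(4, 4, 3)); sel[, , 2] <- 1
  expect_equal(gated_aggregation(levels, sel), levels[[2]])

  expect_error(gated_aggregation(levels, rand_fm(4, 4, 2)), "levels")
})

test_that("focal modulation composes query, context and gates as documented", {
  set.seed(17)
  cfg <- focal_config(8, L = 2)
  w <- sealscope:::init_focal_weights(cfg)
  x <- rand_fm(4, 4, 8)

  # independent per-location evaluation assembled from the component oracles
  q <- oracle_conv2d(x, w$q$w, w$q$b)
  z <- oracle_conv2d(x, w$fz$w, w$fz$b)
  lv <- list()
  for (l in 1:2) {
    dw <- w$dw[[l]]
    zz <- array(0, dim(z))
    for (c in seq_len(8)) zz[, , c] <- oracle_conv2d(z[, , c, drop = FALSE],
                                                     dw[, , , c, drop = FALSE])
    z <- gelu(zz)
    lv[[l]] <- z
  }
  lv[[3]] <- array(rep(apply(z, 3, mean), each = 16), dim(z))
  g <- oracle_conv2d(x, w$fg$w, w$fg$b)
  ctx <- oracle_gated_agg(lv, g)
  m <- oracle_conv2d(ctx, w$h$w, w$h$b)
  ref <- oracle_conv2d(q * m, w$proj$w, w$proj$b)
  expect_lt(max(abs(focal_modulation(x, cfg, w) - ref)), 1e-8)

  # gates forced to zero with zero modulator/projection bias -> all-zero map
  wz <- w
  wz$fg$w[] <- 0; wz$fg$b[] <- 0; wz$h$b[] <- 0; wz$proj$b[] <- 0
  expect_equal(max(abs(focal_modulation(x, cfg, wz))), 0)

  # drop-in shape contract at the backbone tail position
  cfg256 <- focal_config(256)
  w256 <- sealscope:::init_focal_weights(cfg256)
  expect_equal(dim(focal_modulation(rand_fm(15, 15, 256), cfg256, w256)),
               c(15, 15, 256))
})

test_that("the ELAN partial-convolution branch degenerates and saves parameters", {
  set.seed(18)
  spec_std <- elan_spec(32, 16)
  spec_p <- elan_spec(32, 16, pconv_swap = 1, r = 1 / 4)
  expect_equal(spec_p$pconv$c_p, 16)  # prefix capped at the branch width

  w <- sealscope:::init_elan_weights(spec_std)
  wp <- w
  wp$chain[[1]] <- list(w = w$chain[[1]]$w)
  wz <- w; wz$chain[[1]]$b[] <- 0  # standard block with that bias zeroed
  x <- rand_fm(6, 6, 32)
  expect_equal(elan_forward(x, spec_p, wp), elan_forward(x, spec_std, wz))

  expect_lt(block_params(spec_p), block_params(spec_std))
  expect_equal(block_params(spec_std) - block_params(spec_p), 16)  # the bias

  y <- elan_forward(rand_fm(10, 10, 32), spec_std, w)
  expect_equal(dim(y), c(10, 10, 64))
  expect_error(elan_spec(32, 16, pconv_swap = 9), "chain")
})

test_that("parameter counts are monotone in the processed-channel count", {
  counts <- vapply(c(4, 8, 12, 16), function(cp)
    block_params(pconv_spec(16, c_p = cp)), numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("blocks are deterministic given fixed weights and input", {
  set.seed(19)
  cfg <- focal_config(8, L = 2)
  w <- sealscope:::init_focal_weights(cfg)
  x <- rand_fm(5, 5, 8)
  expect_identical(focal_modulation(x, cfg, w), focal_modulation(x, cfg, w))
})
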