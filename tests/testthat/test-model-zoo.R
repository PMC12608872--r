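test_that("parameter counts are exact functions of the spec, frozen by regression", {
  counts <- vapply(c("yolov10n", "f_yolov10", "ff_yolov10",
                     "yolov7", "yolov7_a", "pp_yolov7"),
                   function(m) count_parameters(build_model(m, nc = 1))$total,
                   numeric(1))
  expect_identical(unname(counts),
                   c(2265363, 1780323, 1888742, 36479926, 37023248, 37023184))
  # the dual-assignment training head doubles the v10 head parameters
  expect_identical(count_parameters(build_yolov10n(1, head = "full"))$total,
                   2694806)
})

test_that("counts are invariant to input resolution and monotone in class count", {
  for (m in c("ff_yolov10", "yolov7")) {
    a <- count_parameters(build_model(m, nc = 1, resolution = 480))$total
    b <- count_parameters(build_model(m, nc = 1, resolution = 640))$total
    expect_identical(a, b)
  }
  n1 <- count_parameters(build_yolov10n(nc = 1))$total
  n3 <- count_parameters(build_yolov10n(nc = 3))$total
  expect_gt(n3, n1)
  expect_error(build_yolov10n(1, resolution = 481), "divisible")
})

test_that("module A and module B deltas are independently reproducible and additive", {
  v7 <- count_parameters(build_yolov7(1))$total
  va <- count_parameters(build_yolov7_a(1))$total
  vab <- count_parameters(build_pp_yolov7(1))$total

  # module B: exactly the folded bias of the swapped CBS convolution
  g_a <- build_yolov7_a(1); g_ab <- build_pp_yolov7(1)
  site_a <- g_a$nodes[[7]]; site_ab <- g_ab$nodes[[7]]
  expect_identical(site_a$kind, "conv")
  expect_identical(site_ab$kind, "pconv")
  d_b <- sealscope:::node_count(site_ab) - sealscope:::node_count(site_a)
  expect_identical(vab - va, d_b)
  expect_identical(d_b, -64)

  # module A: the sum of the added layers plus the head growth
  added <- setdiff(seq_along(g_a$nodes), seq_len(76))
  base <- build_yolov7(1)
  per_new <- vapply(g_a$nodes[added], sealscope:::node_count, numeric(1))
  # nodes 102..131 of the augmented graph replicate baseline nodes 77..105
  dup <- vapply(base$nodes[77:106], sealscope:::node_count, numeric(1))
  d_a <- sum(per_new) - sum(dup)
  expect_identical(va - v7, d_a)
  expect_identical((va - v7) + (vab - va), vab - v7)
})

test_that("a serialized graph rebuilds to an identical parameter report", {
  g <- build_ff_yolov10(1)
  f <- tempfile(fileext = ".yaml")
  write_model_spec(g, f)
  g2 <- read_model_spec(f)
  r1 <- count_parameters(g)
  r2 <- count_parameters(g2)
  expect_identical(r1$total, r2$total)
  expect_identical(r1$per_layer$params, r2$per_layer$params)
})

test_that("detection grids follow strides 8/16/32 (and 4 for the small-target scale)", {
  sh <- sealscope:::graph_shapes(build_yolov10n(1, 480))
  grids <- sh[[length(sh)]]
  expect_equal(lapply(grids, function(g) g[1:2]),
               list(c(60, 60), c(30, 30), c(15, 15)))
  sh7 <- sealscope:::graph_shapes(build_pp_yolov7(1, 480))
  grids7 <- sh7[[length(sh7)]]
  expect_equal(vapply(grids7, `[`, numeric(1), 1), c(120, 60, 30, 15))
  # three scales for the baseline ground-station model
  expect_length(sealscope:::graph_shapes(build_yolov7(1, 480))[[106]], 3)
})

test_that("built graphs run forward and emit per-scale maps of the contracted sizes", {
  g <- init_weights(build_ff_yolov10(1, 480), seed = 4)
  x <- array(runif(480 * 480 * 3), c(480, 480, 3))
  out <- forward(g, x)
  expect_equal(lapply(out, dim),
               list(c(60, 60, 65), c(30, 30, 65), c(15, 15, 65)))
  expect_true(all(vapply(out, function(o) all(is.finite(o)), TRUE)))

  g7 <- init_weights(build_pp_yolov7(1, 96), seed = 5)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  out7 <- forward(g7, x)
  expect_equal(vapply(out7, function(o) dim(o)[1], numeric(1)), c(24, 12, 6, 3))
  expect_equal(dim(out7[[1]])[3], 18)  # na * (5 + nc)
})

test_that("reparameterized head branches fuse exactly", {
  set.seed(21)
  w <- repconv_weights(16, 16)   # includes the identity branch
  x <- rand_fm(7, 7, 16)
  expect_lt(max(abs(repconv_forward(x, w) - repconv_forward(x, w, fused = TRUE))),
            1e-5)
  w2 <- repconv_weights(8, 16)   # no identity branch
  x2 <- rand_fm(5, 5, 8)
  expect_lt(max(abs(repconv_forward(x2, w2) - repconv_forward(x2, w2, fused = TRUE))),
            1e-5)
  # fused form has the deploy parameter count
  f <- repconv_fuse(w2)
  expect_equal(length(f$w) + length(f$b),
               sealscope:::node_count(sealscope:::nd("repconv", 1,
                                                     c1 = 8L, c2 = 16L)))
})
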