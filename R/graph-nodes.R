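# Layer nodes of a detector graph.
#
# Each node is list(kind, from, args). Parameter counts are pure functions of
# (kind, args) and come in two conventions:
#   * train  -- the training graph: convolutions are bias-free and followed by
#               batch normalization whose two affine terms are counted;
#               reparameterizable convolutions carry all branches.
#   * deploy -- the inference graph: batch norm folded into the convolution
#               (one bias per output channel), reparameterizable convolutions
#               fused to a single biased convolution.
# The deploy convention is what the package reports as "the" parameter count
# of a detector, matching how deployed model sizes are quoted in the field.

cnt_cv <- function(c1, c2, k = 1L, g = 1L, mode = "deploy", bn = TRUE, bias = !bn) {
  w <- k * k * (c1 %/% g) * c2
  if (bn) w + if (mode == "train") 2L * c2 else c2
  else w + if (bias) c2 else 0L
}

cnt_bottleneck <- function(c, mode) 2L * cnt_cv(c, c, 3L, mode = mode)

cnt_c2f <- function(c1, c2, n, mode) {
  ch <- c2 %/% 2L
  cnt_cv(c1, 2L * ch, mode = mode) + cnt_cv((2L + n) * ch, c2, mode = mode) +
    n * cnt_bottleneck(ch, mode)
}

cnt_c2f_faster <- function(c1, c2, n, mode) {
  ch <- c2 %/% 2L
  fb <- 9L * (ch %/% 4L)^2 + cnt_cv(ch, 2L * ch, mode = mode) + 2L * ch * ch
  cnt_cv(c1, 2L * ch, mode = mode) + cnt_cv((2L + n) * ch, c2, mode = mode) + n * fb
}

cnt_repvggdw <- function(ed, mode) {
  if (mode == "deploy") 49L * ed + ed
  else 49L * ed + 2L * ed + 9L * ed + 2L * ed
}

cnt_cib <- function(c, lk, mode) {
  mid <- if (lk) cnt_repvggdw(2L * c, mode) else cnt_cv(2L * c, 2L * c, 3L, g = 2L * c, mode = mode)
  cnt_cv(c, c, 3L, g = c, mode = mode) + cnt_cv(c, 2L * c, mode = mode) + mid +
    cnt_cv(2L * c, c, mode = mode) + cnt_cv(c, c, 3L, g = c, mode = mode)
}

cnt_c2fcib <- function(c1, c2, n, lk, mode) {
  ch <- c2 %/% 2L
  cnt_cv(c1, 2L * ch, mode = mode) + cnt_cv((2L + n) * ch, c2, mode = mode) +
    n * cnt_cib(ch, lk, mode)
}

cnt_attention <- function(dim, mode) {
  num_heads <- max(1L, dim %/% 64L)
  key_dim <- (dim %/% num_heads) %/% 2L
  h <- dim + 2L * key_dim * num_heads
  cnt_cv(dim, h, mode = mode) + cnt_cv(dim, dim, mode = mode) +
    cnt_cv(dim, dim, 3L, g = dim, mode = mode)
}

cnt_psa <- function(c1, mode) {
  c <- c1 %/% 2L
  cnt_cv(c1, 2L * c, mode = mode) + cnt_cv(2L * c, c1, mode = mode) +
    cnt_attention(c, mode) +
    cnt_cv(c, 2L * c, mode = mode) + cnt_cv(2L * c, c, mode = mode)
}

cnt_focal <- function(c, L, kernels) {
  # four biased linear projections (query, context, modulator, output), the
  # gate projection, and bias-free depthwise levels; no normalization, so
  # train and deploy counts coincide
  4L * (c * c + c) + c * (L + 1L) + (L + 1L) + sum(kernels^2) * c
}

cnt_detect_v10 <- function(ch, nc, dual, mode) {
  reg_max <- 16L
  c2 <- max(16L, ch[1] %/% 4L, 4L * reg_max)
  c3 <- max(ch[1], min(nc, 100L))
  box <- sum(vapply(ch, function(x)
    cnt_cv(x, c2, 3L, mode = mode) + cnt_cv(c2, c2, 3L, mode = mode) +
      c2 * 4L * reg_max + 4L * reg_max, numeric(1)))
  cls <- sum(vapply(ch, function(x)
    cnt_cv(x, x, 3L, g = x, mode = mode) + cnt_cv(x, c3, mode = mode) +
      cnt_cv(c3, c3, 3L, g = c3, mode = mode) + cnt_cv(c3, c3, mode = mode) +
      c3 * nc + nc, numeric(1)))
  (box + cls) * (if (dual) 2L else 1L) + reg_max  # + integral-projection kernel
}

cnt_detect_v7 <- function(ch, nc, na, implicits) {
  no <- na * (nc + 5L)
  sum(vapply(ch, function(x) x * no + no, numeric(1))) +
    if (implicits) sum(ch) + length(ch) * no else 0L
}

node_count <- function(node, mode = "deploy") {
  a <- node$args
  switch(node$kind,
    input = , maxpool = , upsample = , concat = 0,
    conv = cnt_cv(a$c1, a$c2, a$k, a$g %||% 1L, mode, bn = a$bn %||% TRUE),
    pconv = 9L * a$cp^2,
    sppf = cnt_cv(a$c1, a$c1 %/% 2L, mode = mode) +
           cnt_cv((a$c1 %/% 2L) * 4L, a$c2, mode = mode),
    sppcspc = {
      c_ <- a$c2
      cnt_cv(a$c1, c_, mode = mode) + cnt_cv(a$c1, c_, mode = mode) +
        cnt_cv(c_, c_, 3L, mode = mode) + cnt_cv(c_, c_, mode = mode) +
        cnt_cv(4L * c_, c_, mode = mode) + cnt_cv(c_, c_, 3L, mode = mode) +
        cnt_cv(2L * c_, a$c2, mode = mode)
    },
    c2f = cnt_c2f(a$c1, a$c2, a$n, mode),
    c2f_faster = cnt_c2f_faster(a$c1, a$c2, a$n, mode),
    c2fcib = cnt_c2fcib(a$c1, a$c2, a$n, a$lk, mode),
    scdown = cnt_cv(a$c1, a$c2, mode = mode) +
             cnt_cv(a$c2, a$c2, a$k, g = a$c2, mode = mode),
    psa = cnt_psa(a$c1, mode),
    focal = cnt_focal(a$c, a$L, a$kernels),
    repconv = if (mode == "deploy") 9L * a$c1 * a$c2 + a$c2
              else 9L * a$c1 * a$c2 + 2L * a$c2 + a$c1 * a$c2 + 2L * a$c2 +
                   if (a$c1 == a$c2) 2L * a$c1 else 0L,
    detect_v10 = cnt_detect_v10(a$ch, a$nc, a$dual, mode),
    detect_v7 = cnt_detect_v7(a$ch, a$nc, a$na %||% 3L, a$implicits %||% FALSE),
    stop("unknown node kind: ", node$kind, call. = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- shape inference ---------------------------------------------------------

node_out_shape <- function(node, ins) {
  a <- node$args
  one <- ins[[1]]
  sp <- function(s, h, w, c) c(h, w, c)
  switch(node$kind,
    input = one,
    conv = c(ceiling(one[1] / (a$s %||% 1L)), ceiling(one[2] / (a$s %||% 1L)), a$c2),
    pconv = one,
    maxpool = {
      s <- a$s %||% a$k
      p <- a$pad %||% 0L
      c(((one[1] + 2L * p - a$k) %/% s) + 1L, ((one[2] + 2L * p - a$k) %/% s) + 1L, one[3])
    },
    upsample = c(one[1] * (a$scale %||% 2L), one[2] * (a$scale %||% 2L), one[3]),
    concat = c(one[1], one[2], sum(vapply(ins, `[`, numeric(1), 3L))),
    sppf = c(one[1], one[2], a$c2),
    sppcspc = c(one[1], one[2], a$c2),
    c2f = , c2f_faster = , c2fcib = c(one[1], one[2], a$c2),
    scdown = c(ceiling(one[1] / (a$s %||% 2L)), ceiling(one[2] / (a$s %||% 2L)), a$c2),
    psa = one,
    focal = one,
    repconv = c(one[1], one[2], a$c2),
    detect_v10 = lapply(ins, function(s) c(s[1], s[2], 64L + a$nc)),
    detect_v7 = lapply(ins, function(s) c(s[1], s[2], (a$na %||% 3L) * (a$nc + 5L))),
    stop("unknown node kind: ", node$kind, call. = FALSE)
  )
}

# ---- deterministic weight initialization (deploy-form) -----------------------

init_cv <- function(c1, c2, k = 1L, g = 1L, sd = 0.2 / k)
  list(w = rand_arr(c(k, k, c1 %/% g, c2), sd = sd), b = stats::rnorm(c2, sd = 0.02))

node_init <- function(node) {
  a <- node$args
  switch(node$kind,
    input = , maxpool = , upsample = , concat = NULL,
    conv = init_cv(a$c1, a$c2, a$k, a$g %||% 1L),
    pconv = list(w = rand_arr(c(a$k, a$k, a$cp, a$cp), sd = 0.1)),
    sppf = list(cv1 = init_cv(a$c1, a$c1 %/% 2L),
                cv2 = init_cv((a$c1 %/% 2L) * 4L, a$c2)),
    sppcspc = {
      c_ <- a$c2
      list(cv1 = init_cv(a$c1, c_), cv2 = init_cv(a$c1, c_),
           cv3 = init_cv(c_, c_, 3L), cv4 = init_cv(c_, c_),
           cv5 = init_cv(4L * c_, c_), cv6 = init_cv(c_, c_, 3L),
           cv7 = init_cv(2L * c_, a$c2))
    },
    c2f = {
      ch <- a$c2 %/% 2L
      list(cv1 = init_cv(a$c1, 2L * ch), cv2 = init_cv((2L + a$n) * ch, a$c2),
           m = lapply(seq_len(a$n), function(i)
             list(cv1 = init_cv(ch, ch, 3L), cv2 = init_cv(ch, ch, 3L))))
    },
    c2f_faster = init_c2f_faster_weights(c2f_faster_spec(a$c1, a$c2, a$n)),
    c2fcib = {
      ch <- a$c2 %/% 2L
      list(cv1 = init_cv(a$c1, 2L * ch), cv2 = init_cv((2L + a$n) * ch, a$c2),
           m = lapply(seq_len(a$n), function(i) list(
             dw1 = init_cv(ch, ch, 3L, g = ch),
             pw1 = init_cv(ch, 2L * ch),
             mid = if (a$lk) init_cv(2L * ch, 2L * ch, 7L, g = 2L * ch)
                   else init_cv(2L * ch, 2L * ch, 3L, g = 2L * ch),
             pw2 = init_cv(2L * ch, ch),
             dw2 = init_cv(ch, ch, 3L, g = ch))))
    },
    scdown = list(cv1 = init_cv(a$c1, a$c2),
                  cv2 = init_cv(a$c2, a$c2, a$k, g = a$c2)),
    psa = {
      c <- a$c1 %/% 2L
      num_heads <- max(1L, c %/% 64L)
      key_dim <- (c %/% num_heads) %/% 2L
      h <- c + 2L * key_dim * num_heads
      list(cv1 = init_cv(a$c1, 2L * c), cv2 = init_cv(2L * c, a$c1),
           qkv = init_cv(c, h), proj = init_cv(c, c), pe = init_cv(c, c, 3L, g = c),
           ffn1 = init_cv(c, 2L * c), ffn2 = init_cv(2L * c, c),
           meta = list(num_heads = num_heads, key_dim = key_dim,
                       head_dim = c %/% num_heads))
    },
    focal = init_focal_weights(focal_config(a$c, a$L, a$kernels)),
    repconv = init_cv(a$c1, a$c2, 3L),
    detect_v10 = {
      reg_max <- 16L
      c2 <- max(16L, a$ch[1] %/% 4L, 4L * reg_max)
      c3 <- max(a$ch[1], min(a$nc, 100L))
      one_set <- function() list(
        box = lapply(a$ch, function(x) list(cv1 = init_cv(x, c2, 3L),
                                            cv2 = init_cv(c2, c2, 3L),
                                            out = init_cv(c2, 4L * reg_max))),
        cls = lapply(a$ch, function(x) list(dw1 = init_cv(x, x, 3L, g = x),
                                            pw1 = init_cv(x, c3),
                                            dw2 = init_cv(c3, c3, 3L, g = c3),
                                            pw2 = init_cv(c3, c3),
                                            out = init_cv(c3, a$nc))))
      w <- list(one2one = one_set(), dfl = 0:(reg_max - 1L))
      if (a$dual) w$one2many <- one_set()
      w
    },
    detect_v7 = lapply(a$ch, function(x) {
      no <- (a$na %||% 3L) * (a$nc + 5L)
      w <- init_cv(x, no)
      if (isTRUE(a$implicits)) {
        w$ia <- stats::rnorm(x, sd = 0.02)
        w$im <- 1 + stats::rnorm(no, sd = 0.02)
      }
      w
    }),
    stop("unknown node kind: ", node$kind, call. = FALSE)
  )
}

# ---- forward -----------------------------------------------------------------

fwd_cv <- function(x, w, k, s = 1L, g = 1L, act = silu)
  act(conv2d(x, w$w, w$b, stride = s, pad = "same", groups = g))

fwd_bottleneck <- function(x, w, shortcut) {
  y <- fwd_cv(fwd_cv(x, w$cv1, 3L), w$cv2, 3L)
  if (shortcut) x + y else y
}

fwd_c2f <- function(x, w, a) {
  ch <- a$c2 %/% 2L
  y <- fwd_cv(x, w$cv1, 1L)
  parts <- list(y[, , seq_len(ch), drop = FALSE], y[, , ch + seq_len(ch), drop = FALSE])
  cur <- parts[[2]]
  for (i in seq_len(a$n)) {
    cur <- fwd_bottleneck(cur, w$m[[i]], isTRUE(a$shortcut))
    parts[[length(parts) + 1L]] <- cur
  }
  fwd_cv(concat_c(parts), w$cv2, 1L)
}

fwd_cib <- function(x, w, a, ch) {
  y <- fwd_cv(x, w$dw1, 3L, g = ch)
  y <- fwd_cv(y, w$pw1, 1L)
  y <- fwd_cv(y, w$mid, if (a$lk) 7L else 3L, g = 2L * ch)
  y <- fwd_cv(y, w$pw2, 1L)
  y <- fwd_cv(y, w$dw2, 3L, g = ch)
  x + y
}

fwd_c2fcib <- function(x, w, a) {
  ch <- a$c2 %/% 2L
  y <- fwd_cv(x, w$cv1, 1L)
  parts <- list(y[, , seq_len(ch), drop = FALSE], y[, , ch + seq_len(ch), drop = FALSE])
  cur <- parts[[2]]
  for (i in seq_len(a$n)) {
    cur <- fwd_cib(cur, w$m[[i]], a, ch)
    parts[[length(parts) + 1L]] <- cur
  }
  fwd_cv(concat_c(parts), w$cv2, 1L)
}

fwd_attention <- function(x, w) {
  d <- dim(x); n <- d[1] * d[2]
  meta <- w$meta
  qkv <- conv2d(x, w$qkv$w, w$qkv$b)                   # h x w x (nh*(2kd+hd))
  qkvm <- matrix(qkv, n, dim(qkv)[3])
  per <- 2L * meta$key_dim + meta$head_dim
  out <- matrix(0, n, meta$num_heads * meta$head_dim)
  scale <- meta$key_dim^-0.5
  for (hh in seq_len(meta$num_heads)) {
    off <- (hh - 1L) * per
    q <- qkvm[, off + seq_len(meta$key_dim), drop = FALSE]
    k <- qkvm[, off + meta$key_dim + seq_len(meta$key_dim), drop = FALSE]
    v <- qkvm[, off + 2L * meta$key_dim + seq_len(meta$head_dim), drop = FALSE]
    att <- q %*% t(k) * scale
    att <- exp(att - apply(att, 1L, max))
    att <- att / rowSums(att)
    out[, (hh - 1L) * meta$head_dim + seq_len(meta$head_dim)] <- att %*% v
  }
  vmap <- array(qkvm[, as.vector(vapply(seq_len(meta$num_heads), function(hh)
    (hh - 1L) * per + 2L * meta$key_dim + seq_len(meta$head_dim), integer(meta$head_dim))),
    drop = FALSE], d)
  y <- array(out, d) + conv2d(vmap, w$pe$w, w$pe$b, groups = d[3])
  conv2d(y, w$proj$w, w$proj$b)
}

fwd_psa <- function(x, w, a) {
  c <- a$c1 %/% 2L
  y <- fwd_cv(x, w$cv1, 1L)
  aa <- y[, , seq_len(c), drop = FALSE]
  bb <- y[, , c + seq_len(c), drop = FALSE]
  bb <- bb + fwd_attention(bb, w)
  bb <- bb + conv2d(fwd_cv(bb, w$ffn1, 1L), w$ffn2$w, w$ffn2$b)
  fwd_cv(concat_c(list(aa, bb)), w$cv2, 1L)
}

fwd_sppf <- function(x, w, a) {
  y <- fwd_cv(x, w$cv1, 1L)
  p1 <- max_pool2d(y, 5L, 1L, 2L)
  p2 <- max_pool2d(p1, 5L, 1L, 2L)
  p3 <- max_pool2d(p2, 5L, 1L, 2L)
  fwd_cv(concat_c(list(y, p1, p2, p3)), w$cv2, 1L)
}

fwd_sppcspc <- function(x, w) {
  x1 <- fwd_cv(fwd_cv(fwd_cv(x, w$cv1, 1L), w$cv3, 3L), w$cv4, 1L)
  pools <- lapply(c(5L, 9L, 13L), function(k) max_pool2d(x1, k, 1L, k %/% 2L))
  y1 <- fwd_cv(fwd_cv(concat_c(c(list(x1), pools)), w$cv5, 1L), w$cv6, 3L)
  y2 <- fwd_cv(x, w$cv2, 1L)
  fwd_cv(concat_c(list(y1, y2)), w$cv7, 1L)
}

fwd_detect_v10 <- function(xs, w, a) {
  reg_max <- 16L
  lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    box <- w$one2one$box[[i]]
    cls <- w$one2one$cls[[i]]
    b <- fwd_cv(fwd_cv(x, box$cv1, 3L), box$cv2, 3L)
    b <- conv2d(b, box$out$w, box$out$b)
    cdim <- dim(x)[3]
    cl <- fwd_cv(x, cls$dw1, 3L, g = cdim)
    cl <- fwd_cv(cl, cls$pw1, 1L)
    c3 <- dim(cl)[3]
    cl <- fwd_cv(cl, cls$dw2, 3L, g = c3)
    cl <- fwd_cv(cl, cls$pw2, 1L)
    cl <- conv2d(cl, cls$out$w, cls$out$b)
    concat_c(list(b, cl))
  })
}

fwd_detect_v7 <- function(xs, w, a) {
  lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    wi <- w[[i]]
    if (!is.null(wi$ia)) x <- x + rep(wi$ia, each = dim(x)[1] * dim(x)[2])
    y <- conv2d(x, wi$w, wi$b)
    if (!is.null(wi$im)) y <- y * rep(wi$im, each = dim(y)[1] * dim(y)[2])
    y
  })
}

node_forward <- function(node, ins, w) {
  a <- node$args
  x <- ins[[1]]
  switch(node$kind,
    input = x,
    conv = fwd_cv(x, w, a$k, a$s %||% 1L, a$g %||% 1L,
                  act_fun(a$act %||% "silu")),
    pconv = pconv_act_forward(x, pconv_spec(a$c, c_p = a$cp, k = a$k), w, silu),
    maxpool = max_pool2d(x, a$k, a$s %||% a$k, a$pad %||% 0L),
    upsample = upsample_nearest(x, a$scale %||% 2L),
    concat = concat_c(ins),
    sppf = fwd_sppf(x, w, a),
    sppcspc = fwd_sppcspc(x, w),
    c2f = fwd_c2f(x, w, a),
    c2f_faster = c2f_faster(x, c2f_faster_spec(a$c1, a$c2, a$n), w),
    c2fcib = fwd_c2fcib(x, w, a),
    scdown = conv2d(fwd_cv(x, w$cv1, 1L), w$cv2$w, w$cv2$b,
                    stride = a$s %||% 2L, pad = "same", groups = a$c2),
    psa = fwd_psa(x, w, a),
    focal = focal_modulation(x, focal_config(a$c, a$L, a$kernels), w),
    repconv = fwd_cv(x, w, 3L),
    detect_v10 = fwd_detect_v10(ins, w, a),
    detect_v7 = fwd_detect_v7(ins, w, a),
    stop("unknown node kind: ", node$kind, call. = FALSE)
  )
}
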