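#' Partial convolution specification
#'
#' A partial convolution (PConv) applies a dense `k x k` convolution to a
#' contiguous prefix of `c_p` of the `c` input channels and passes the
#' remaining `c - c_p` channels through untouched. The processed fraction
#' `r = c_p / c` defaults to 1/4, the standard channel selection ratio; the
#' contiguous-prefix choice follows the memory-locality argument of the
#' FasterNet design.
#'
#' @param c total number of channels.
#' @param c_p number of processed channels (`1 <= c_p <= c`).
#' @param k odd kernel size.
#' @param r processed ratio used when `c_p` is not given.
#' @param bias should the processed slice carry a bias? FasterNet-style PConv
#'   is bias-free (the default).
#' @return an object of class `pconv_spec`.
#' @examples
#' pconv_spec(64)            # c_p = 16
#' pconv_spec(64, c_p = 64)  # degenerates to a dense convolution
#' @export
pconv_spec <- function(c, c_p = NULL, k = 3L, r = 1 / 4, bias = FALSE) {
  if (is.null(c_p)) c_p <- as.integer(round(c * r))
  c <- as.integer(c); c_p <- as.integer(c_p); k <- as.integer(k)
  if (k %% 2L == 0L) stop("PConv kernel size must be odd", call. = FALSE)
  if (c_p < 1L || c_p > c)
    stop("processed channels c_p must satisfy 1 <= c_p <= c", call. = FALSE)
  structure(list(c = c, c_p = c_p, k = k, r = c_p / c, bias = bias),
            class = "pconv_spec")
}

#' Partial convolution forward pass
#'
#' @param x feature map with `spec$c` channels.
#' @param spec a [pconv_spec()].
#' @param weights list with `w` (`k x k x c_p x c_p` array) and optionally `b`
#'   (length `c_p`) when `spec$bias` is `TRUE`.
#' @return feature map of the same shape: channels `1..c_p` hold the
#'   convolution of input channels `1..c_p`, channels `c_p+1..c` are copied
#'   through bit-identically.
#' @export
pconv_forward <- function(x, spec, weights) {
  stopifnot(inherits(spec, "pconv_spec"))
  d <- dim(x)
  if (d[3] != spec$c)
    stop(sprintf("input has %d channels, spec expects %d", d[3], spec$c), call. = FALSE)
  cp <- spec$c_p
  y <- x
  y[, , seq_len(cp)] <- conv2d(x[, , seq_len(cp), drop = FALSE], weights$w,
                               b = if (spec$bias) weights$b else NULL)
  y
}

#' Memory-access accounting for partial convolution
#'
#' Full-form memory access cost of a standard convolution,
#' `h*w*2c + k^2*c^2`, against the partial form `h*w*2c_p + k^2*c_p^2`,
#' together with the dominant-term ratio `c_p / c` (the `h*w*2c` terms
#' dominate for realistic spatial sizes, so the partial cost approaches
#' `c_p / c` of the standard one; at the default ratio of 1/4 this is
#' one-fourth of the cost).
#'
#' @param h,w spatial dimensions.
#' @param c,c_p total and processed channel counts.
#' @param k kernel size.
#' @return list with `standard_cost`, `pconv_cost` and `ratio`.
#' @export
pconv_memory_access <- function(h, w, c, c_p, k = 3L) {
  stopifnot(h > 0, w > 0, c > 0, c_p > 0, k > 0)
  list(standard_cost = h * w * 2 * c + k^2 * c^2,
       pconv_cost    = h * w * 2 * c_p + k^2 * c_p^2,
       ratio         = c_p / c)
}

#' Pointwise (1x1) convolution
#' @param x feature map.
#' @param w `1 x 1 x c_in x c_out` (or `c_in x c_out` matrix) weight.
#' @param b optional bias.
#' @return feature map with `c_out` channels.
#' @export
pwconv <- function(x, w, b = NULL) {
  if (is.matrix(w)) w <- array(w, c(1L, 1L, nrow(w), ncol(w)))
  conv2d(x, w, b)
}

#' FasterNet block
#'
#' The FasterNet residual unit: a partial convolution for spatial mixing,
#' followed by a pointwise expansion (by `expand`, default 2), channel
#' normalization and activation -- applied only after the intermediate
#' pointwise layer -- then a bias-free pointwise projection back to `c`
#' channels, added to the input. Requires equal input and output channels so
#' the residual addition is well defined.
#'
#' @param x feature map with `spec$c` channels.
#' @param spec a `fasternet_spec` from [fasternet_spec()].
#' @param weights list with `pconv` (list `w`), `w1`, `g1`, `b1` (expansion
#'   weight and folded norm scale/shift) and `w2` (projection weight).
#' @return feature map of the same shape as `x`.
#' @export
fasternet_block <- function(x, spec, weights) {
  d <- dim(x)
  if (d[3] != spec$c)
    stop("FasterNet block requires in-channels == out-channels", call. = FALSE)
  h <- pconv_forward(x, spec$pconv, weights$pconv)
  h <- pwconv(h, weights$w1)
  h <- channel_norm(h, weights$g1, weights$b1)
  h <- spec$act(h)
  h <- pwconv(h, weights$w2)
  x + h
}

#' @rdname fasternet_block
#' @param c channel count.
#' @param expand pointwise expansion factor.
#' @param n_div channel divisor for the partial convolution (`c_p = c / n_div`).
#' @param act activation applied after the intermediate pointwise layer
#'   (GeLU per the FasterNet design).
#' @export
fasternet_spec <- function(c, expand = 2L, n_div = 4L, act = gelu) {
  structure(list(c = as.integer(c), expand = as.integer(expand),
                 pconv = pconv_spec(c, c_p = max(1L, c %/% n_div)),
                 act = act),
            class = "fasternet_spec")
}

#' C2f-Faster block
#'
#' The lightweight replacement for the C2f stage: an input pointwise
#' convolution, a channel split into two halves, `n` FasterNet blocks chained
#' on the second half with every intermediate output retained (the C2f
#' dense-concat wiring), concatenation of the `2 + n` parts and an output
#' pointwise convolution to the declared channel count. Hidden width is
#' `c2 %/% 2`; any odd remainder is absorbed by the output projection.
#'
#' @param x feature map with `c1` channels.
#' @param spec `c2f_faster_spec`.
#' @param weights nested weight list (`cv1`, `cv2` with `w`,`b`; `blocks`: one
#'   FasterNet weight list per repeat).
#' @return feature map with `spec$c2` channels.
#' @export
c2f_faster <- function(x, spec, weights) {
  ch <- spec$hidden
  y <- silu(pwconv(x, weights$cv1$w, weights$cv1$b))
  parts <- list(y[, , seq_len(ch), drop = FALSE],
                y[, , ch + seq_len(ch), drop = FALSE])
  cur <- parts[[2]]
  for (i in seq_len(spec$n)) {
    cur <- fasternet_block(cur, spec$block, weights$blocks[[i]])
    parts[[length(parts) + 1L]] <- cur
  }
  silu(pwconv(concat_c(parts), weights$cv2$w, weights$cv2$b))
}

#' @rdname c2f_faster
#' @param c1,c2 input and output channels.
#' @param n number of FasterNet repeats (`n = 0` reduces the block to
#'   conv-split-concat-conv).
#' @export
c2f_faster_spec <- function(c1, c2, n = 1L) {
  hidden <- c2 %/% 2L
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2), n = as.integer(n),
                 hidden = as.integer(hidden), block = fasternet_spec(hidden)),
            class = "c2f_faster_spec")
}

#' Focal modulation configuration
#'
#' Configuration of the attention-free focal modulation operator: `L` focal
#' levels of depthwise convolutions with growing odd kernels, a gate map with
#' exactly `L + 1` channels (one per level plus the global level), and four
#' linear (1x1) projections over channels: the query `q`, the context
#' embedding `f_z`, the gates `f_g` and the modulator map `h`, plus an output
#' projection. The default configuration uses `L = 2` levels with kernels 3
#' and 5, which is the configuration whose parameter budget matches the
#' published onboard model.
#'
#' @param c channel count.
#' @param L number of focal levels (`L >= 0`).
#' @param kernels odd depthwise kernel sizes, length `L`.
#' @return a `focal_config`.
#' @export
focal_config <- function(c, L = 2L, kernels = seq(3L, by = 2L, length.out = L)) {
  L <- as.integer(L)
  if (L < 0L) stop("focal_levels must be >= 0", call. = FALSE)
  kernels <- as.integer(kernels)
  if (length(kernels) != L) stop("need one kernel per focal level", call. = FALSE)
  if (L > 0L && any(kernels %% 2L == 0L)) stop("focal kernels must be odd", call. = FALSE)
  structure(list(c = as.integer(c), L = L, kernels = kernels),
            class = "focal_config")
}

#' Hierarchical contextualization
#'
#' Builds the focal context pyramid: `Z0 = f_z(x)`; then
#' `Z_l = GeLU(DWConv_l(Z_{l-1}))` for `l = 1..L`; finally the global level
#' `Z_{L+1}` is the spatial average of `Z_L` broadcast back to the grid.
#' Returns levels `1..L+1` (for `L = 0` the single returned level is the
#' per-channel mean of `Z0` at every location).
#'
#' @param x feature map with `cfg$c` channels.
#' @param cfg a [focal_config()].
#' @param weights list with `fz` (list `w`, `b`) and `dw` (list of depthwise
#'   `k x k x 1 x c` weights, one per level).
#' @return list of `L + 1` feature maps, each the shape of `x`.
#' @export
hierarchical_contextualize <- function(x, cfg, weights) {
  stopifnot(inherits(cfg, "focal_config"))
  z <- pwconv(x, weights$fz$w, weights$fz$b)
  levels <- vector("list", cfg$L + 1L)
  for (l in seq_len(cfg$L)) {
    z <- gelu(conv2d(z, weights$dw[[l]], stride = 1L, pad = "same", groups = cfg$c))
    levels[[l]] <- z
  }
  levels[[cfg$L + 1L]] <- global_avg_broadcast(z)
  levels
}

#' Gated aggregation of focal levels
#'
#' Per-location weighted sum of the context levels: the level-`l` gate slice
#' (a scalar per location) is broadcast across channels and multiplied into
#' level `l`; the products are summed over the `L + 1` levels.
#'
#' @param levels list of feature maps sharing `h x w x c`.
#' @param gates feature map `h x w x (L + 1)`.
#' @return feature map `h x w x c`.
#' @export
gated_aggregation <- function(levels, gates) {
  nl <- length(levels)
  if (dim(gates)[3] != nl)
    stop(sprintf("gate map has %d channels but there are %d levels",
                 dim(gates)[3], nl), call. = FALSE)
  d <- dim(levels[[1]])
  out <- array(0, d)
  for (l in seq_len(nl)) {
    if (!identical(dim(levels[[l]]), d))
      stop("all context levels must share h x w x c", call. = FALSE)
    out <- out + levels[[l]] * as.vector(gates[, , l])  # broadcast over channels
  }
  out
}

#' Focal modulation forward pass
#'
#' The full operator `y_i = q(x_i) * h(sum_l g_i^l z_i^l)` followed by an
#' output projection: the query projection modulated elementwise by the
#' gate-aggregated context pyramid. Composes
#' [hierarchical_contextualize()] and [gated_aggregation()] with gates
#' `G = f_g(x)`. Output shape equals input shape, so the block is a drop-in
#' replacement for the spatial-pyramid-pooling position at the backbone tail.
#'
#' @param x feature map with `cfg$c` channels.
#' @param cfg a [focal_config()].
#' @param weights list with `fz`, `dw` (see [hierarchical_contextualize()]),
#'   `q`, `fg`, `h`, `proj` (each a list `w`, `b`).
#' @return feature map of the same shape as `x`.
#' @export
focal_modulation <- function(x, cfg, weights) {
  q <- pwconv(x, weights$q$w, weights$q$b)
  levels <- hierarchical_contextualize(x, cfg, weights)
  gates <- pwconv(x, weights$fg$w, weights$fg$b)
  ctx <- gated_aggregation(levels, gates)
  m <- pwconv(ctx, weights$h$w, weights$h$b)
  pwconv(q * m, weights$proj$w, weights$proj$b)
}

#' ELAN aggregation block
#'
#' The efficient layer aggregation unit of the ground-station detector: two
#' pointwise entry branches, a chain of `n3` dense 3x3 convolutions on the
#' second branch, dense concatenation of the taps and a pointwise output
#' projection. `elan_spec()` describes the block; setting `pconv_swap` to a
#' chain index replaces that CBS convolution with a bias-free partial
#' convolution whose processed width is `r` of the block's aggregate
#' (concatenated) width -- on a `mid`-wide branch with aggregate width
#' `4 * mid` and `r = 1/4` the processed prefix spans the whole branch, so
#' only the folded bias is dropped.
#'
#' @param x feature map with `spec$c1` channels.
#' @param spec an `elan_spec`.
#' @param weights list: `b1`, `b2` (entry convs), `chain` (list per 3x3), `out`.
#' @return feature map with `spec$c2` channels.
#' @export
elan_forward <- function(x, spec, weights) {
  b1 <- silu(pwconv(x, weights$b1$w, weights$b1$b))
  b2 <- silu(pwconv(x, weights$b2$w, weights$b2$b))
  taps <- list(b1, b2)
  cur <- b2
  for (i in seq_len(spec$n3)) {
    if (i == spec$pconv_swap) {
      # the swap replaces the convolution inside the CBS unit; the activation
      # stays, applied to the processed slice
      cur <- pconv_act_forward(cur, spec$pconv, weights$chain[[i]], silu)
    } else {
      cur <- silu(conv2d(cur, weights$chain[[i]]$w, weights$chain[[i]]$b))
    }
    taps[[length(taps) + 1L]] <- cur
  }
  keep <- if (spec$dense) rev(taps) else list(taps[[spec$n3 + 2L]], taps[[spec$n3]],
                                              taps[[2]], taps[[1]])
  silu(pwconv(concat_c(keep), weights$out$w, weights$out$b))
}

# channel widths along the second-branch chain: the ELAN-W (dense) variant
# halves the width at the first chain convolution, the backbone variant keeps it
elan_chain_widths <- function(spec) {
  if (spec$dense) c(spec$mid, rep(spec$mid %/% 2L, spec$n3))
  else rep(spec$mid, spec$n3 + 1L)
}

#' @rdname elan_forward
#' @param c1,c2 block input and output channels.
#' @param mid branch width.
#' @param n3 number of 3x3 convolutions on the second branch.
#' @param dense if `TRUE` every tap is concatenated (the ELAN-W wiring of the
#'   detector neck); if `FALSE` only taps 2 and 4 of the chain plus the two
#'   entries (the backbone wiring).
#' @param pconv_swap 0 for the standard block, otherwise the 1-based index of
#'   the chain convolution replaced by the partial convolution.
#' @param r processed-channel ratio of the swapped partial convolution,
#'   relative to the aggregate width.
#' @export
elan_spec <- function(c1, mid, n3 = 4L, c2 = NULL, dense = FALSE,
                      pconv_swap = 0L, r = 1 / 4) {
  mid <- as.integer(mid); n3 <- as.integer(n3)
  agg <- if (dense) 2L * mid + n3 * (mid %/% 2L) else 4L * mid
  if (is.null(c2)) c2 <- agg
  if (pconv_swap > n3) stop("pconv_swap exceeds the chain length", call. = FALSE)
  if (pconv_swap > 0L && dense)
    stop("the partial-convolution swap targets the backbone wiring", call. = FALSE)
  cp <- min(as.integer(round(agg * r)), mid)  # prefix cannot exceed branch width
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2), mid = mid,
                 n3 = n3, dense = dense,
                 pconv_swap = as.integer(pconv_swap),
                 pconv = if (pconv_swap > 0L) pconv_spec(mid, c_p = cp) else NULL),
            class = "elan_spec")
}

#' Learnable-scalar counts of the stand-alone blocks
#'
#' Deployed (inference-time) parameter counts: convolutions carry a folded
#' bias in place of batch-norm affine terms; FasterNet partial convolutions
#' and pointwise projections are bias-free as in the reference design.
#'
#' @param spec a `pconv_spec`, `fasternet_spec`, `c2f_faster_spec`,
#'   `focal_config` or `elan_spec`.
#' @return integer number of scalars.
#' @export
block_params <- function(spec) {
  cnt_conv <- function(c1, c2, k = 1L, g = 1L, bias = TRUE)
    k * k * (c1 %/% g) * c2 + if (bias) c2 else 0L
  if (inherits(spec, "pconv_spec"))
    return(spec$k^2 * spec$c_p^2 + if (spec$bias) spec$c_p else 0L)
  if (inherits(spec, "fasternet_spec")) {
    c <- spec$c; e <- spec$expand
    return(block_params(spec$pconv) + cnt_conv(c, e * c) + e * c * c)
  }
  if (inherits(spec, "c2f_faster_spec")) {
    ch <- spec$hidden
    return(cnt_conv(spec$c1, 2L * ch) + cnt_conv((2L + spec$n) * ch, spec$c2) +
             spec$n * block_params(spec$block))
  }
  if (inherits(spec, "focal_config")) {
    c <- spec$c
    return(cnt_conv(c, c) +                       # q
             cnt_conv(c, c) +                     # f_z
             cnt_conv(c, spec$L + 1L) +           # gates
             sum(spec$kernels^2) * c +            # depthwise levels, bias-free
             cnt_conv(c, c) +                     # modulator h
             cnt_conv(c, c))                      # output projection
  }
  if (inherits(spec, "elan_spec")) {
    widths <- elan_chain_widths(spec)
    chain_w <- vapply(seq_len(spec$n3), function(i) {
      if (i == spec$pconv_swap) block_params(spec$pconv)
      else cnt_conv(widths[i], widths[i + 1L], 3L)
    }, numeric(1))
    agg <- if (spec$dense) 2L * spec$mid + sum(widths[-1L]) else 4L * spec$mid
    return(cnt_conv(spec$c1, spec$mid) * 2L + sum(chain_w) + cnt_conv(agg, spec$c2))
  }
  stop("unknown block spec", call. = FALSE)
}

# partial convolution with an activation on the processed slice (the form a
# PConv takes when it replaces the convolution of a CBS unit)
pconv_act_forward <- function(x, spec, weights, act = silu) {
  y <- x
  cp <- spec$c_p
  y[, , seq_len(cp)] <- act(conv2d(x[, , seq_len(cp), drop = FALSE], weights$w,
                                   b = if (spec$bias) weights$b else NULL))
  y
}

# deterministic weight helpers ------------------------------------------------

rand_arr <- function(dims, sd = 0.1) array(stats::rnorm(prod(dims), sd = sd), dims)

init_pconv_weights <- function(spec) {
  w <- list(w = rand_arr(c(spec$k, spec$k, spec$c_p, spec$c_p)))
  if (spec$bias) w$b <- stats::rnorm(spec$c_p, sd = 0.1)
  w
}

init_fasternet_weights <- function(spec) {
  c <- spec$c; e <- spec$expand
  list(pconv = init_pconv_weights(spec$pconv),
       w1 = rand_arr(c(1, 1, c, e * c)),
       g1 = stats::rnorm(e * c, mean = 1, sd = 0.05),
       b1 = stats::rnorm(e * c, sd = 0.1),
       w2 = rand_arr(c(1, 1, e * c, c)))
}

init_c2f_faster_weights <- function(spec) {
  ch <- spec$hidden
  list(cv1 = list(w = rand_arr(c(1, 1, spec$c1, 2 * ch)), b = stats::rnorm(2 * ch, sd = 0.1)),
       cv2 = list(w = rand_arr(c(1, 1, (2 + spec$n) * ch, spec$c2)),
                  b = stats::rnorm(spec$c2, sd = 0.1)),
       blocks = lapply(seq_len(spec$n), function(i) init_fasternet_weights(spec$block)))
}

init_focal_weights <- function(cfg) {
  c <- cfg$c
  pw <- function(ci, co) list(w = rand_arr(c(1, 1, ci, co)), b = stats::rnorm(co, sd = 0.1))
  list(q = pw(c, c), fz = pw(c, c), fg = pw(c, cfg$L + 1L),
       dw = lapply(cfg$kernels, function(k) rand_arr(c(k, k, 1, c))),
       h = pw(c, c), proj = pw(c, c))
}

init_elan_weights <- function(spec) {
  pw <- function(ci, co) list(w = rand_arr(c(1, 1, ci, co)), b = stats::rnorm(co, sd = 0.1))
  widths <- elan_chain_widths(spec)
  chain <- lapply(seq_len(spec$n3), function(i) {
    if (i == spec$pconv_swap) init_pconv_weights(spec$pconv)
    else list(w = rand_arr(c(3, 3, widths[i], widths[i + 1L])),
              b = stats::rnorm(widths[i + 1L], sd = 0.1))
  })
  agg <- if (spec$dense) 2L * spec$mid + sum(widths[-1L]) else 4L * spec$mid
  list(b1 = pw(spec$c1, spec$mid), b2 = pw(spec$c1, spec$mid), chain = chain,
       out = pw(agg, spec$c2))
}
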