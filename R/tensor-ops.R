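#' Feature maps
#'
#' A feature map is a plain 3-dimensional numeric array with dimensions
#' `height x width x channels` (HWC layout, fixed package-wide). These helpers
#' validate and construct feature maps; all neural operators in the package
#' consume and produce arrays in this layout.
#'
#' @param x numeric array.
#' @return `feature_map()` returns the validated array; `is_feature_map()` a
#'   logical scalar.
#' @examples
#' x <- feature_map(array(rnorm(8 * 8 * 3), c(8, 8, 3)))
#' dim(x)
#' @export
feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("a feature map must be an h x w x c array", call. = FALSE)
  if (any(dim(x) < 1L)) stop("feature map dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(x))) stop("feature map values must be finite", call. = FALSE)
  x
}

#' @rdname feature_map
#' @export
is_feature_map <- function(x) is.array(x) && length(dim(x)) == 3L && all(is.finite(x))

# zero-pad an HWC array spatially
pad_hwc <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

#' Dense 2-D convolution on an HWC array
#'
#' Reference convolution used by every block in the package. Weights are stored
#' as a `k x k x c_in/groups x c_out` array; the implementation lowers the
#' input to column form and multiplies through BLAS. Stride-1 "same" padding
#' preserves spatial dimensions.
#'
#' @param x feature map (`h x w x c_in`).
#' @param w weight array `k x k x c_in/groups x c_out`.
#' @param b optional bias vector of length `c_out`.
#' @param stride integer stride.
#' @param pad `"same"` (default, `(k-1)/2` zeros) or an integer pad width.
#' @param groups number of channel groups; `groups = c_in = c_out` is a
#'   depthwise convolution.
#' @return feature map `h' x w' x c_out`.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = "same", groups = 1L) {
  d <- dim(x); dw <- dim(w)
  k <- dw[1]
  if (dw[1] != dw[2]) stop("only square kernels are supported", call. = FALSE)
  if (k %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
  cin <- d[3]; cout <- dw[4]
  if (dw[3] * groups != cin)
    stop(sprintf("weight expects %d input channels, got %d", dw[3] * groups, cin),
         call. = FALSE)
  p <- if (identical(pad, "same")) (k - 1L) %/% 2L else as.integer(pad)
  xp <- pad_hwc(x, p)
  ho <- (d[1] + 2L * p - k) %/% stride + 1L
  wo <- (d[2] + 2L * p - k) %/% stride + 1L
  ys <- seq.int(1L, by = stride, length.out = ho)
  xs <- seq.int(1L, by = stride, length.out = wo)

  if (groups == 1L) {
    cols <- matrix(0, ho * wo, k * k * cin)
    idx <- 1L
    for (ci in seq_len(cin)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
      cols[, idx] <- xp[ys + dy, xs + dx, ci]
      idx <- idx + 1L
    }
    # column order of `cols` is (dy, dx, ci); build the matching weight matrix
    wm <- matrix(0, k * k * cin, cout)
    idx <- 1L
    for (ci in seq_len(cin)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
      wm[idx, ] <- w[dy, dx, ci, ]
      idx <- idx + 1L
    }
    out <- cols %*% wm
  } else if (groups == cin && cin == cout) {
    # depthwise
    out <- matrix(0, ho * wo, cout)
    for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
      sl <- xp[ys + dy, xs + dx, , drop = FALSE]
      out <- out + matrix(sl, ho * wo, cin) *
        rep(w[dy + 1L, dx + 1L, 1L, ], each = ho * wo)
    }
  } else {
    cg_in <- cin %/% groups; cg_out <- cout %/% groups
    out <- matrix(0, ho * wo, cout)
    for (g in seq_len(groups)) {
      xi <- xp[, , ((g - 1L) * cg_in + 1L):(g * cg_in), drop = FALSE]
      wi <- w[, , , ((g - 1L) * cg_out + 1L):(g * cg_out), drop = FALSE]
      sub <- conv2d(xi[ys[1]:(ys[ho] + k - 1L), xs[1]:(xs[wo] + k - 1L), , drop = FALSE],
                    wi, NULL, stride = stride, pad = 0L, groups = 1L)
      out[, ((g - 1L) * cg_out + 1L):(g * cg_out)] <- matrix(sub, ho * wo, cg_out)
    }
  }
  if (!is.null(b)) out <- out + rep(b, each = ho * wo)
  array(out, c(ho, wo, cout))
}

#' Activation functions
#'
#' SiLU (`x * sigmoid(x)`, the YOLO-family default) and the tanh approximation
#' of GeLU (used inside FasterNet blocks and the focal-modulation context
#' encoder).
#' @param x numeric array.
#' @return array of the same shape.
#' @export
silu <- function(x) x / (1 + exp(-x))

#' @rdname silu
#' @export
gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))

act_fun <- function(name) {
  switch(name,
         silu = silu, gelu = gelu, none = identity,
         stop("unknown activation: ", name, call. = FALSE))
}

#' Channel-wise affine normalization
#'
#' Inference-form batch normalization: a learned per-channel scale and shift.
#' At deployment the running statistics and affine terms of batch
#' normalization fold into this form (and further into the preceding
#' convolution's weights and bias, which is how the package counts deployed
#' parameters).
#' @param x feature map.
#' @param gamma,beta per-channel scale and shift vectors.
#' @return feature map of the same shape.
#' @export
channel_norm <- function(x, gamma, beta) {
  d <- dim(x)
  n <- d[1] * d[2]
  array(matrix(x, n, d[3]) * rep(gamma, each = n) + rep(beta, each = n), d)
}

#' Max pooling
#'
#' @param x feature map.
#' @param k pooling window.
#' @param stride stride (defaults to `k`).
#' @param pad zero-padding width (`k %/% 2` gives the "same" pooling used in
#'   SPPF/SPPCSPC); padded cells are treated as `-Inf`.
#' @return pooled feature map.
#' @export
max_pool2d <- function(x, k = 2L, stride = k, pad = 0L) {
  d <- dim(x)
  xp <- if (pad > 0L) {
    out <- array(-Inf, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
    out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
    out
  } else x
  dp <- dim(xp)
  ho <- (dp[1] - k) %/% stride + 1L
  wo <- (dp[2] - k) %/% stride + 1L
  ys <- seq.int(1L, by = stride, length.out = ho)
  xs <- seq.int(1L, by = stride, length.out = wo)
  out <- matrix(-Inf, ho * wo, d[3])
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    out <- pmax(out, matrix(xp[ys + dy, xs + dx, , drop = FALSE], ho * wo, d[3]))
  }
  array(out, c(ho, wo, d[3]))
}

#' Nearest-neighbour upsampling
#' @param x feature map.
#' @param scale integer upscaling factor.
#' @return feature map with `scale`-times larger spatial dimensions.
#' @export
upsample_nearest <- function(x, scale = 2L) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = scale), rep(seq_len(d[2]), each = scale), , drop = FALSE]
}

#' Concatenate feature maps along channels
#' @param ... feature maps sharing spatial dimensions.
#' @return concatenated feature map.
#' @export
concat_c <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.array(xs[[1]])) xs <- xs[[1]]
  ds <- lapply(xs, dim)
  if (length(unique(vapply(ds, function(d) paste(d[1:2], collapse = "x"), ""))) != 1L)
    stop("spatial dimensions differ across concat inputs", call. = FALSE)
  array(unlist(lapply(xs, as.vector), use.names = FALSE),
        c(ds[[1]][1], ds[[1]][2], sum(vapply(ds, `[`, 1L, 3L))))
}

#' Global average pooling broadcast back to the input grid
#' @param x feature map.
#' @return feature map of the same shape where every spatial location holds the
#'   per-channel mean.
#' @export
global_avg_broadcast <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3]))
  array(rep(m, each = d[1] * d[2]), d)
}
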