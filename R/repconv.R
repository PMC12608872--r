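#' Reparameterizable convolution
#'
#' The head convolution of the ground-station detector family: at training
#' time a sum of a dense 3x3 branch, a 1x1 branch and (when channel counts
#' match) an identity branch, each followed by channel normalization; at
#' deployment the three branches fuse algebraically into a single biased 3x3
#' convolution with identical outputs. `repconv_weights()` draws a random
#' train-form weight set, `repconv_fuse()` folds it, and `repconv_forward()`
#' evaluates either form.
#'
#' @param c1,c2 input and output channels.
#' @return `repconv_weights()`: train-form weight list (`w3`, `g3`, `b3`,
#'   `w1`, `g1`, `b1` and, if `c1 == c2`, `gid`, `bid`).
#' @export
repconv_weights <- function(c1, c2) {
  w <- list(w3 = rand_arr(c(3, 3, c1, c2), sd = 0.1),
            g3 = stats::rnorm(c2, 1, 0.05), b3 = stats::rnorm(c2, sd = 0.05),
            w1 = rand_arr(c(1, 1, c1, c2), sd = 0.1),
            g1 = stats::rnorm(c2, 1, 0.05), b1 = stats::rnorm(c2, sd = 0.05))
  if (c1 == c2) {
    w$gid <- stats::rnorm(c2, 1, 0.05)
    w$bid <- stats::rnorm(c2, sd = 0.05)
  }
  w
}

#' @rdname repconv_weights
#' @param w train-form weight list.
#' @export
repconv_fuse <- function(w) {
  d <- dim(w$w3)
  c1 <- d[3]; c2 <- d[4]
  wf <- array(0, d)
  for (o in seq_len(c2)) wf[, , , o] <- w$w3[, , , o] * w$g3[o]
  for (o in seq_len(c2)) wf[2, 2, , o] <- wf[2, 2, , o] + w$w1[1, 1, , o] * w$g1[o]
  b <- w$b3 + w$b1
  if (!is.null(w$gid)) {
    for (o in seq_len(c2)) wf[2, 2, o, o] <- wf[2, 2, o, o] + w$gid[o]
    b <- b + w$bid
  }
  list(w = wf, b = b)
}

#' @rdname repconv_weights
#' @param x feature map.
#' @param fused evaluate the fused single-convolution form?
#' @export
repconv_forward <- function(x, w, fused = FALSE) {
  if (fused || !is.null(w$w) ) {
    f <- if (!is.null(w$w)) w else repconv_fuse(w)
    return(silu(conv2d(x, f$w, f$b)))
  }
  y <- channel_norm(conv2d(x, w$w3), w$g3, w$b3) +
    channel_norm(conv2d(x, w$w1), w$g1, w$b1)
  if (!is.null(w$gid)) y <- y + channel_norm(x, w$gid, w$bid)
  silu(y)
}
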