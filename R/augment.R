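# Augmentation operators: spatial geometric transforms, edge padding and
# background (canvas) scaling, each with the exact box-update rule.

#' Augmentation operators
#'
#' `augmentation_op()` describes one operator; [augment()] applies it to an
#' image and its boxes, keeping annotations consistent with the pixel
#' transform: boxes are mapped (for affine ops, by transforming the four
#' corners and taking the enclosing rectangle), clipped to the canvas, and
#' dropped when degenerate.
#'
#' @param kind `"hflip"`, `"vflip"`, `"affine"`, `"pad"` or `"scale"`.
#' @param angle rotation in degrees (affine; about the canvas centre).
#' @param scale isotropic scale factor (affine and scale kinds).
#' @param pad edge padding width in pixels (pad kind; all four sides).
#' @param fill fill value for exposed canvas.
#' @return an `augmentation_op`.
#' @export
augmentation_op <- function(kind = c("hflip", "vflip", "affine", "pad", "scale"),
                            angle = 0, scale = 1, pad = 0L, fill = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, angle = angle, scale = scale,
                 pad = as.integer(pad), fill = fill),
            class = "augmentation_op")
}

# inverse-map nearest-neighbour affine warp about the canvas centre
warp_affine <- function(image, angle, scale, fill) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse transform: rotate by -th, scale by 1/scale
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  sx <- (cos(th) * xx + sin(th) * yy) / scale + cx
  sy <- (-sin(th) * xx + cos(th) * yy) / scale + cy
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  idx <- (pmin(pmax(sj, 1), w) - 1L) * h + pmin(pmax(si, 1), h)
  out <- array(fill, d)
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    o <- rep(fill, h * w)
    o[ok] <- plane[idx[ok]]
    out[, , ch] <- matrix(o, h, w)
  }
  out
}

map_corners_affine <- function(boxes, h, w, angle, scale) {
  th <- angle * pi / 180
  cy <- h / 2; cx <- w / 2
  t(apply(boxes, 1, function(b) {
    xs <- c(b[1], b[3], b[1], b[3]) - cx
    ys <- c(b[2], b[2], b[4], b[4]) - cy
    nx <- scale * (cos(th) * xs - sin(th) * ys) + cx
    ny <- scale * (sin(th) * xs + cos(th) * ys) + cy
    c(min(nx), min(ny), max(nx), max(ny))
  }))
}

#' Apply an augmentation operator
#'
#' @param image `h x w x 3` array.
#' @param boxes ground-truth data frame (see [ground_truth()]).
#' @param op an [augmentation_op()].
#' @param seed unused for the deterministic operators; kept for a uniform
#'   signature with stochastic augmentation policies.
#' @return list with transformed `image` and `boxes`.
#' @export
augment <- function(image, boxes, op, seed = 1L) {
  stopifnot(inherits(op, "augmentation_op"))
  d <- dim(image); h <- d[1]; w <- d[2]
  fill <- op$fill %||% stats::median(image)
  bm <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE])
  out <- switch(op$kind,
    hflip = {
      img <- image[, rev(seq_len(w)), , drop = FALSE]
      if (nrow(bm)) bm <- cbind(w - bm[, 3], bm[, 2], w - bm[, 1], bm[, 4])
      list(img, bm, h, w)
    },
    vflip = {
      img <- image[rev(seq_len(h)), , , drop = FALSE]
      if (nrow(bm)) bm <- cbind(bm[, 1], h - bm[, 4], bm[, 3], h - bm[, 2])
      list(img, bm, h, w)
    },
    affine = {
      img <- warp_affine(image, op$angle, op$scale, fill)
      if (nrow(bm)) bm <- map_corners_affine(bm, h, w, op$angle, op$scale)
      list(img, bm, h, w)
    },
    pad = {
      p <- op$pad
      img <- array(fill, c(h + 2L * p, w + 2L * p, d[3]))
      img[p + seq_len(h), p + seq_len(w), ] <- image
      if (nrow(bm)) bm <- bm + p
      list(img, bm, h + 2L * p, w + 2L * p)
    },
    scale = {
      nh <- max(1L, round(h * op$scale)); nw <- max(1L, round(w * op$scale))
      si <- pmin(h, pmax(1L, round(seq_len(nh) / op$scale)))
      sj <- pmin(w, pmax(1L, round(seq_len(nw) / op$scale)))
      img <- image[si, sj, , drop = FALSE]
      if (nrow(bm)) bm <- bm * op$scale
      list(img, bm, nh, nw)
    })
  img <- out[[1]]; bm <- out[[2]]; nh <- out[[3]]; nw <- out[[4]]
  if (length(bm) && nrow(bm)) {
    bm[, c(1, 3)] <- pmin(pmax(bm[, c(1, 3)], 0), nw)
    bm[, c(2, 4)] <- pmin(pmax(bm[, c(2, 4)], 0), nh)
    valid <- bm[, 1] < bm[, 3] & bm[, 2] < bm[, 4]
    if (any(!valid)) warning(sum(!valid), " degenerate box(es) dropped")
    boxes <- boxes[valid, , drop = FALSE]
    bm <- bm[valid, , drop = FALSE]
    boxes[, c("x_min", "y_min", "x_max", "y_max")] <- bm
  } else {
    boxes <- boxes[integer(0), , drop = FALSE]
  }
  list(image = img, boxes = boxes)
}
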