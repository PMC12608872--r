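# Independent oracles, written as plain summation loops so they share no code
# path with the package implementations they check.

# dense same-padding convolution by direct per-pixel summation
oracle_conv2d <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)[1]; co <- dim(w)[4]
  p <- (k - 1) / 2
  out <- array(0, c(d[1], d[2], co))
  for (oy in seq_len(d[1])) for (ox in seq_len(d[2])) for (oc in seq_len(co)) {
    acc <- if (is.null(b)) 0 else b[oc]
    for (dy in seq_len(k)) for (dx in seq_len(k)) for (ic in seq_len(d[3])) {
      iy <- oy + dy - 1 - p; ix <- ox + dx - 1 - p
      if (iy >= 1 && iy <= d[1] && ix >= 1 && ix <= d[2])
        acc <- acc + x[iy, ix, ic] * w[dy, dx, ic, oc]
    }
    out[oy, ox, oc] <- acc
  }
  out
}

# gated aggregation by an explicit location/channel/level triple loop
oracle_gated_agg <- function(levels, gates) {
  d <- dim(levels[[1]])
  out <- array(0, d)
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) for (c in seq_len(d[3]))
    for (l in seq_along(levels))
      out[y, x, c] <- out[y, x, c] + gates[y, x, l] * levels[[l]][y, x, c]
  out
}

# all-points interpolated AP from a TP/FP label sequence (already sorted by
# descending confidence) via explicit rectangle summation over the envelope
oracle_ap <- function(labels, n_gt) {
  if (!length(labels) || n_gt == 0) return(0)
  tp <- cumsum(labels); fp <- cumsum(!labels)
  prec <- tp / (tp + fp); rec <- tp / n_gt
  r <- c(0, rec); p <- c(1, prec)
  for (i in (length(p) - 1):1) p[i] <- max(p[i], p[i + 1])
  area <- 0
  for (i in 2:length(r)) area <- area + (r[i] - r[i - 1]) * p[i]
  area
}

# greedy confidence-ordered matcher, re-derived independently
oracle_match <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  lab <- logical(nd); used <- logical(ng)
  for (i in order(-dets$conf)) {
    best <- 0; bj <- 0
    for (j in seq_len(ng)) {
      if (used[j]) next
      if (gts$image_id[j] != dets$image_id[i]) next
      o <- iou(as.numeric(dets[i, 1:4]), as.numeric(gts[j, 1:4]))
      if (o > best) { best <- o; bj <- j }
    }
    if (bj > 0 && best >= thr) { lab[i] <- TRUE; used[bj] <- TRUE }
  }
  list(TP = sum(lab), FP = nd - sum(lab), FN = ng - sum(lab), labels = lab)
}

rand_fm <- function(h, w, c) array(rnorm(h * w * c), c(h, w, c))

rand_boxes_df <- function(n, canvas = 100, conf = TRUE, image_id = 1L) {
  x1 <- runif(n, 0, canvas - 12); y1 <- runif(n, 0, canvas - 12)
  w <- runif(n, 4, 25); h <- runif(n, 4, 25)
  d <- data.frame(x_min = x1, y_min = y1,
                  x_max = pmin(canvas, x1 + w), y_max = pmin(canvas, y1 + h),
                  stringsAsFactors = FALSE)
  if (conf) d$conf <- runif(n)
  d$class_id <- rep("Phoca largha", n)
  d$image_id <- rep(image_id, n)
  d
}
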