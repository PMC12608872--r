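# Synthetic UAV nadir scenes: small speckled elliptical targets on a
# low-contrast mudflat background, with altitude-dependent target scale and
# four weather regimes. The generator exists so that the detection metrics,
# the two-stage pipeline and the annotation tooling are testable without the
# restricted field imagery; it emulates the low-contrast failure mode
# (grey-black dorsal speckle against muddy substrate) as a difficulty knob.

#' Scene specification
#'
#' @param canvas canvas side length in pixels (square frames).
#' @param n_targets number of seals to plant (>= 0).
#' @param altitude `"15m"` or `"20m"`; the altitude proxy sets the target
#'   major-axis range (28-44 px and 20-32 px respectively at 480 px canvas,
#'   keeping targets in the small-object band).
#' @param contrast mean luminance separation between target bodies and the
#'   background, in `[0, 1]`; low values emulate the hard mudflat regime.
#' @param overlap maximum allowed IoU between planted target boxes.
#' @param base_hue background RGB triple (muddy substrate).
#' @param mottling amplitude of the low-frequency background mottling.
#' @param weather one of `"sunny"`, `"reflective"`, `"foggy"`, `"overcast"`.
#' @param seed RNG seed; generation is fully reproducible from (spec, seed).
#' @return a `scene_spec`.
#' @export
scene_spec <- function(canvas = 480L, n_targets = 5L, altitude = c("15m", "20m"),
                       contrast = 0.25, overlap = 0.1,
                       base_hue = c(0.52, 0.45, 0.38), mottling = 0.06,
                       weather = "sunny", seed = 1L) {
  altitude <- match.arg(altitude)
  stopifnot(n_targets >= 0, canvas >= 32, contrast >= 0, contrast <= 1)
  structure(list(canvas = as.integer(canvas), n_targets = as.integer(n_targets),
                 altitude = altitude, contrast = contrast, overlap = overlap,
                 base_hue = base_hue, mottling = mottling, weather = weather,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

target_axis_range <- function(spec) {
  r <- if (spec$altitude == "15m") c(28, 44) else c(20, 32)
  r * spec$canvas / 480
}

# smooth random field in [-1, 1] via blurred white noise
smooth_field <- function(n, sigma) {
  f <- matrix(stats::rnorm(n * n), n, n)
  f <- EBImage::gblur(f, sigma = sigma)
  f / max(abs(f), 1e-9)
}

#' Generate one synthetic scene
#'
#' Renders the mudflat background (base hue plus low-frequency mottling and
#' fine grain), plants `n_targets` rotated speckled ellipses subject to the
#' overlap budget, applies the spec's weather effect, and returns the image
#' together with one ground-truth box per target -- the minimum enclosing
#' rectangle of the rendered body pixels. Deterministic for a fixed spec.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`canvas x canvas x 3`, values in `[0, 1]`),
#'   `boxes` (a [ground_truth()] data frame) and `mask` (the noise-free
#'   integer label map of planted targets, for oracle checks).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$canvas
  mott <- smooth_field(n, sigma = n / 24) * spec$mottling
  grain <- matrix(stats::rnorm(n * n, sd = 0.015), n, n)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- spec$base_hue[ch] + mott + grain

  mask <- matrix(0L, n, n)
  boxes <- NULL
  ax <- target_axis_range(spec)
  placed <- list()
  for (t in seq_len(spec$n_targets)) {
    ok <- FALSE
    for (try in 1:200) {
      a <- stats::runif(1, ax[1], ax[2]) / 2            # semi-major
      b <- a * stats::runif(1, 0.38, 0.55)              # seals are elongated
      phi <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a + 2, n - a - 2)
      cy <- stats::runif(1, a + 2, n - a - 2)
      # candidate footprints are expanded by 1 px, so an overlap budget of 0
      # guarantees a separating gap between rendered bodies
      cand <- c(cx - a - 1, cy - a - 1, cx + a + 1, cy + a + 1)
      clash <- any(vapply(placed, function(p) iou(p, cand) > spec$overlap, TRUE))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible packing: too many non-overlapping targets",
                  call. = FALSE)
    placed[[length(placed) + 1L]] <- cand

    ys <- max(1L, floor(cy - a)):min(n, ceiling(cy + a))
    xs <- max(1L, floor(cx - a)):min(n, ceiling(cx + a))
    gy <- outer(ys - cy, rep(1, length(xs)))
    gx <- outer(rep(1, length(ys)), xs - cx)
    u <- gx * cos(phi) + gy * sin(phi)
    v <- -gx * sin(phi) + gy * cos(phi)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    body <- mean(spec$base_hue) - spec$contrast
    shade <- 1 - 0.25 * ((u / a)^2 + (v / b)^2)         # dorsal shading
    speck <- matrix(stats::rnorm(length(inside), sd = 0.035), nrow(inside))
    spots <- matrix(stats::runif(length(inside)) < 0.06, nrow(inside)) * 0.08
    col <- pmin(1, pmax(0, body * shade + speck + spots))
    for (ch in 1:3) {
      tint <- c(1, 0.98, 0.95)[ch]
      sl <- img[ys, xs, ch]
      sl[inside] <- col[inside] * tint
      img[ys, xs, ch] <- sl
    }
    msl <- mask[ys, xs]
    msl[inside] <- t
    mask[ys, xs] <- msl

    idx <- which(mask == t, arr.ind = TRUE)
    boxes <- rbind(boxes, data.frame(
      x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
      x_max = max(idx[, 2]), y_max = max(idx[, 1]),
      class_id = "Phoca largha", image_id = 1L, stringsAsFactors = FALSE))
  }
  img <- clamp01(img)
  img <- apply_weather(img, weather_effect(spec$weather), seed = spec$seed + 1L)
  if (is.null(boxes))
    boxes <- ground_truth(numeric(0), numeric(0), numeric(0), numeric(0),
                          character(0), integer(0))
  list(image = img, boxes = boxes, mask = mask)
}

#' Weather effects
#'
#' Pixel-space transforms emulating the four survey conditions; annotations
#' are never altered. `sunny` is the reference condition (identity);
#' `foggy` blends toward a bright haze, reducing target/background contrast
#' monotonically in `density`; `reflective` adds bright glare patches;
#' `overcast` applies a global gain/contrast reduction.
#'
#' @param kind condition name.
#' @param density fog density in `[0, 1)`.
#' @param glare_strength,glare_patches glare intensity and patch count.
#' @param gain,contrast overcast global gain and contrast factors.
#' @return a `weather_effect`.
#' @export
weather_effect <- function(kind = c("sunny", "reflective", "foggy", "overcast"),
                           density = 0.5, glare_strength = 0.35,
                           glare_patches = 3L, gain = 0.85, contrast = 0.8) {
  kind <- match.arg(kind)
  structure(list(kind = kind, density = density, glare_strength = glare_strength,
                 glare_patches = as.integer(glare_patches), gain = gain,
                 contrast = contrast),
            class = "weather_effect")
}

#' @rdname weather_effect
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param effect a `weather_effect`.
#' @param seed RNG seed for stochastic effects (glare placement).
#' @export
apply_weather <- function(image, effect, seed = 1L) {
  stopifnot(inherits(effect, "weather_effect"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- switch(effect$kind,
    sunny = image,
    foggy = {
      if (effect$density == 0) image
      else {
        haze <- c(0.85, 0.87, 0.9)
        for (ch in 1:3)
          image[, , ch] <- (1 - effect$density) * image[, , ch] +
            effect$density * haze[ch]
        image
      }
    },
    overcast = {
      m <- mean(image)
      (image - m) * effect$contrast + m * effect$gain
    },
    reflective = {
      n <- dim(image)[1]
      glare <- matrix(0, n, dim(image)[2])
      for (p in seq_len(effect$glare_patches)) {
        cx <- stats::runif(1, 1, dim(image)[2]); cy <- stats::runif(1, 1, n)
        r <- stats::runif(1, n / 12, n / 6)
        gy <- outer(seq_len(n) - cy, rep(1, dim(image)[2]))
        gx <- outer(rep(1, n), seq_len(dim(image)[2]) - cx)
        glare <- glare + exp(-(gx^2 + gy^2) / (2 * r^2))
      }
      glare <- glare / max(glare, 1e-9) * effect$glare_strength
      for (ch in 1:3) image[, , ch] <- image[, , ch] + glare
      image
    })
  clamp01(out)
}

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

#' Target/background contrast statistic
#'
#' Mean absolute luminance difference between target pixels and background
#' pixels, computed from a scene's label mask; used to verify that weather
#' degradations reduce contrast.
#'
#' @param image scene image.
#' @param mask integer label mask from [generate_scene()].
#' @return scalar contrast.
#' @export
scene_contrast <- function(image, mask) {
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  abs(mean(lum[mask > 0]) - mean(lum[mask == 0]))
}
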