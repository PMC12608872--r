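test_that("scene generation is deterministic and respects the target count", {
  sp <- scene_spec(canvas = 160, n_targets = 4, seed = 7)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_equal(nrow(a$boxes), 4)
  expect_true(all(a$boxes$x_min >= 0 & a$boxes$x_max <= 160))

  empty <- generate_scene(scene_spec(canvas = 96, n_targets = 0, seed = 1))
  expect_equal(nrow(empty$boxes), 0)

  # infeasible packing errors out after bounded retries
  expect_error(generate_scene(scene_spec(canvas = 48, n_targets = 150,
                                         overlap = 0, seed = 2)),
               "packing")
})

test_that("mask connected components recover the planted annotations", {
  sp <- scene_spec(canvas = 480, n_targets = 20, contrast = 0.45,
                   mottling = 0.03, overlap = 0, seed = 99)
  sc <- generate_scene(sp)
  lab <- EBImage::bwlabel(sc$mask > 0)
  n <- max(lab)
  expect_equal(n, 20)
  rec <- do.call(rbind, lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
  }))
  # each recovered rectangle matches a planted box with IoU >= 0.95
  ious <- vapply(seq_len(n), function(k)
    max(vapply(seq_len(nrow(sc$boxes)), function(j)
      iou(rec[k, ], as.numeric(sc$boxes[j, 1:4])), numeric(1))), numeric(1))
  expect_true(all(ious >= 0.95))
})

test_that("weather effects are identities at null parameters and fog is monotone", {
  sp <- scene_spec(canvas = 160, n_targets = 5, contrast = 0.35, seed = 3)
  sc <- generate_scene(sp)
  expect_identical(apply_weather(sc$image, weather_effect("foggy", density = 0)),
                   sc$image)
  expect_equal(apply_weather(sc$image,
                             weather_effect("overcast", gain = 1, contrast = 1)),
               sc$image)
  expect_identical(apply_weather(sc$image, weather_effect("sunny")), sc$image)

  cs <- vapply(c(0, 0.5, 0.9), function(d)
    scene_contrast(apply_weather(sc$image, weather_effect("foggy", density = d)),
                   sc$mask), numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("flip and padding augmentations follow the exact box-update rules", {
  sp <- scene_spec(canvas = 128, n_targets = 3, seed = 5)
  sc <- generate_scene(sp)
  fl <- augment(sc$image, sc$boxes, augmentation_op("hflip"))
  expect_equal(fl$boxes$x_min, 128 - sc$boxes$x_max)
  expect_equal(fl$boxes$x_max, 128 - sc$boxes$x_min)
  fl2 <- augment(fl$image, fl$boxes, augmentation_op("hflip"))
  expect_identical(fl2$image, sc$image)                       # involution
  expect_equal(fl2$boxes$x_min, sc$boxes$x_min)

  pd <- augment(sc$image, sc$boxes, augmentation_op("pad", pad = 9))
  expect_equal(dim(pd$image)[1:2], c(146, 146))
  expect_equal(pd$boxes$x_min, sc$boxes$x_min + 9)
  expect_equal(pd$boxes$y_max, sc$boxes$y_max + 9)
})

test_that("affine boxes equal enclosing rectangles of the transformed corners", {
  set.seed(41)
  for (i in 1:100) {
    h <- 120; w <- 120
    # keep boxes in the central region so no transformed corner leaves the
    # canvas (radius 35*sqrt(2)*1.2 < 60): every box survives the clip
    x1 <- runif(3, 35, 70); y1 <- runif(3, 35, 70)
    boxes <- data.frame(x_min = x1, y_min = y1,
                        x_max = x1 + runif(3, 4, 15), y_max = y1 + runif(3, 4, 15),
                        class_id = "Phoca largha", image_id = 1L)
    ang <- runif(1, -15, 15); sc <- runif(1, 0.8, 1.2)
    img <- array(runif(h * w * 3), c(h, w, 3))
    out <- augment(img, boxes, augmentation_op("affine", angle = ang, scale = sc))
    # independent corner mapping via an explicit rotation matrix
    th <- ang * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) * sc
    for (j in seq_len(nrow(boxes))) {
      b <- as.numeric(boxes[j, 1:4])
      corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[1], b[4]), c(b[3], b[4]))
      mapped <- t(R %*% (t(corners) - c(w / 2, h / 2)) + c(w / 2, h / 2))
      want <- c(max(0, min(mapped[, 1])), max(0, min(mapped[, 2])),
                min(w, max(mapped[, 1])), min(h, max(mapped[, 2])))
      expect_equal(as.numeric(out$boxes[j, 1:4]), want, tolerance = 1e-8)
    }
  }
})

test_that("a high-contrast synthetic dataset is solvable by the reference detector", {
  sp <- scene_spec(canvas = 320, n_targets = 6, contrast = 0.45,
                   mottling = 0.03, seed = 11)
  sc <- generate_scene(sp)
  det <- reference_detector()
  rep <- metrics_report(det(sc$image), sc$boxes)
  expect_equal(rep$ap, 1)
  expect_equal(rep$FN, 0)
})
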