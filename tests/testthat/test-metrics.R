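test_that("IoU has the closed-form values", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
})

test_that("greedy matching handles the degenerate cases and preserves TP + FN = |gt|", {
  set.seed(31)
  gts <- rand_boxes_df(6, conf = FALSE)
  dets <- gts
  dets$conf <- 1
  m <- match_detections(dets, gts, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(6, 0, 0))

  m0 <- match_detections(rand_boxes_df(0), gts, 0.5)
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0, 0, 6))

  for (i in 1:50) {
    d <- rand_boxes_df(sample(0:6, 1))
    g <- rand_boxes_df(sample(0:6, 1), conf = FALSE)
    m <- match_detections(d, g, 0.5)
    expect_identical(m$TP + m$FN, nrow(g))
  }
})

test_that("matching agrees with the independent greedy oracle on random instances", {
  set.seed(32)
  for (i in 1:300) {
    d <- rand_boxes_df(sample(1:5, 1), canvas = 60)
    g <- rand_boxes_df(sample(1:5, 1), canvas = 60, conf = FALSE)
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    a <- match_detections(d, g, thr)
    b <- oracle_match(d, g, thr)
    expect_identical(a$labels, b$labels)
  }
})

test_that("precision and recall follow the exact ratios and stated conventions", {
  expect_equal(unname(precision_recall(8, 2, 2)), c(0.8, 0.8))
  expect_equal(unname(precision_recall(0, 0, 5)), c(1, 0))
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("average precision matches hand and oracle envelope integration", {
  # four ground truths; five detections labelled TP/FP/TP/TP/FP by construction
  gts <- ground_truth(c(0, 20, 40, 60), c(0, 0, 0, 0),
                      c(10, 30, 50, 70), c(10, 10, 10, 10))
  dets <- detections(x_min = c(0, 80, 20, 40, 80),
                     y_min = c(0, 80, 0, 0, 40),
                     x_max = c(10, 90, 30, 50, 90),
                     y_max = c(10, 90, 10, 10, 50),
                     conf = c(0.9, 0.8, 0.7, 0.6, 0.5))
  cur <- average_precision(dets, gts, 0.5)
  expect_identical(cur$labels, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(cur$ap, 0.625)                                   # hand value
  expect_equal(cur$ap, oracle_ap(cur$labels, 4))                # oracle value

  # degenerate curves
  perfect <- dets[c(1, 3, 4), ]; perfect$conf <- c(1, 1, 1)
  expect_equal(average_precision(rbind(perfect,
    detections(60, 0, 70, 10, 1)), gts, 0.5)$ap, 1)
  allfp <- dets[c(2, 5), ]
  expect_equal(average_precision(allfp, gts, 0.5)$ap, 0)
})

test_that("AP is rank-only, monotone in IoU threshold, and stable under edits", {
  set.seed(33)
  for (i in 1:25) {
    d <- rand_boxes_df(sample(3:8, 1))
    g <- rand_boxes_df(sample(2:6, 1), conf = FALSE)
    ap1 <- average_precision(d, g, 0.5)$ap
    d2 <- d; d2$conf <- d$conf * 0.37 + 0.01     # order-preserving rescale
    expect_equal(average_precision(d2, g, 0.5)$ap, ap1)

    aps <- vapply(c(0.3, 0.5, 0.7), function(t)
      average_precision(d, g, t)$ap, numeric(1))
    expect_true(all(diff(aps) <= 1e-12))

    # a new lowest-confidence FP never increases AP
    fp <- detections(200, 200, 210, 210, conf = min(d$conf) / 2)
    expect_lte(average_precision(rbind(d, fp), g, 0.5)$ap, ap1 + 1e-12)
    # a new top-confidence TP never decreases it
    if (nrow(g)) {
      tp <- g[1, ]; tp$conf <- max(d$conf) + 0.5
      tp <- tp[, c("x_min", "y_min", "x_max", "y_max", "conf", "class_id", "image_id")]
      g2 <- rbind(g, g[1, ])
      expect_gte(average_precision(rbind(tp, d), g, 0.5)$ap, ap1 - 1e-12)
    }
  }
})

test_that("mAP is the arithmetic mean of per-class APs", {
  expect_equal(mean_average_precision(c(1, 0)), 0.5)
  expect_equal(mean_average_precision(0.742), 0.742)
  expect_error(mean_average_precision(numeric(0)), "class")
})

test_that("condition report computes FP and FN rates per stratum", {
  set.seed(34)
  g <- rand_boxes_df(10, conf = FALSE)
  d <- g; d$conf <- 1
  batches <- list(sunny = list(dets = d, gts = g),
                  foggy = list(dets = d[0, ], gts = g))
  rep <- condition_report(batches)
  expect_equal(rep$fp_rate, c(0, 0))
  expect_equal(rep$fn_rate, c(0, 1))
  expect_equal(rep$n_detections, c(10, 0))
})

test_that("a planted deletion fraction is recovered as the FN rate", {
  set.seed(35)
  n <- 200
  g <- rand_boxes_df(n, canvas = 2000, conf = FALSE)
  drop <- runif(n) < 0.10
  d <- g[!drop, ]; d$conf <- 1
  rep <- condition_report(list(foggy = list(dets = d, gts = g)))
  # binomial tolerance: 3 * sqrt(p(1-p)/n) ~ 0.064
  expect_lt(abs(rep$fn_rate - 0.10), 0.065)
  expect_equal(rep$fn_rate, mean(drop))  # deletions are exact here
})
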