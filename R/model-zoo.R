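# Detector graph builders.
#
# All builders produce deploy-form graphs: batch normalization is folded into
# convolution biases and reparameterizable convolutions are fused, so
# count_parameters()$total reports inference-time model size. The YOLOv10
# family is NMS-free: its deployed graph carries the one-to-one head only
# (head = "full" additionally carries the one-to-many training head, which
# doubles the head parameters).

v10_nodes <- function(nc, c2f_kind = "c2f", tail_kind = "sppf") {
  tail <- if (tail_kind == "focal")
    nd("focal", -1, c = 256L, L = 2L, kernels = c(3L, 5L))
  else nd("sppf", -1, c1 = 256L, c2 = 256L, k = 5L)
  ck <- c2f_kind
  list(
    nd("conv", 0, c1 = 3L, c2 = 16L, k = 3L, s = 2L),                 # 1 P1/2
    nd("conv", -1, c1 = 16L, c2 = 32L, k = 3L, s = 2L),               # 2 P2/4
    nd(ck, -1, c1 = 32L, c2 = 32L, n = 1L, shortcut = TRUE),          # 3
    nd("conv", -1, c1 = 32L, c2 = 64L, k = 3L, s = 2L),               # 4 P3/8
    nd(ck, -1, c1 = 64L, c2 = 64L, n = 2L, shortcut = TRUE),          # 5
    nd("scdown", -1, c1 = 64L, c2 = 128L, k = 3L, s = 2L),            # 6 P4/16
    nd(ck, -1, c1 = 128L, c2 = 128L, n = 2L, shortcut = TRUE),        # 7
    nd("scdown", -1, c1 = 128L, c2 = 256L, k = 3L, s = 2L),           # 8 P5/32
    nd(ck, -1, c1 = 256L, c2 = 256L, n = 1L, shortcut = TRUE),        # 9
    tail,                                                             # 10
    nd("psa", -1, c1 = 256L),                                         # 11
    nd("upsample", -1, scale = 2L),                                   # 12
    nd("concat", c(-1, 7)),                                           # 13
    nd(ck, -1, c1 = 384L, c2 = 128L, n = 1L, shortcut = FALSE),       # 14
    nd("upsample", -1, scale = 2L),                                   # 15
    nd("concat", c(-1, 5)),                                           # 16
    nd(ck, -1, c1 = 192L, c2 = 64L, n = 1L, shortcut = FALSE),        # 17 P3 out
    nd("conv", -1, c1 = 64L, c2 = 64L, k = 3L, s = 2L),               # 18
    nd("concat", c(-1, 14)),                                          # 19
    nd(ck, -1, c1 = 192L, c2 = 128L, n = 1L, shortcut = FALSE),       # 20 P4 out
    nd("scdown", -1, c1 = 128L, c2 = 128L, k = 3L, s = 2L),           # 21
    nd("concat", c(-1, 11)),                                          # 22
    nd("c2fcib", -1, c1 = 384L, c2 = 256L, n = 1L, lk = TRUE),        # 23 P5 out
    nd("detect_v10", c(17, 20, 23), ch = c(64L, 128L, 256L), nc = nc,
       dual = FALSE)                                                  # 24
  )
}

check_res <- function(resolution) {
  if (resolution %% 32L != 0L)
    stop("input resolution must be divisible by 32", call. = FALSE)
  as.integer(resolution)
}

#' Build the baseline onboard detector (YOLOv10, scale n)
#'
#' Standard n-scale NMS-free detector: C2f backbone stages, spatial-channel
#' decoupled downsampling, SPPF and partial self-attention at the backbone
#' tail, three detection scales at strides 8/16/32 with the decoupled
#' box/class head. `head = "deploy"` (default) builds the inference graph
#' with the one-to-one head only; `head = "full"` carries both one-to-one and
#' one-to-many head sets of the consistent dual-assignment scheme.
#'
#' @param nc number of classes (>= 1).
#' @param resolution input resolution, divisible by 32.
#' @param head `"deploy"` or `"full"`.
#' @return a [model_graph()].
#' @export
build_yolov10n <- function(nc = 1L, resolution = 480L, head = c("deploy", "full")) {
  head <- match.arg(head)
  stopifnot(nc >= 1L)
  nodes <- v10_nodes(as.integer(nc))
  nodes[[24]]$args$dual <- head == "full"
  model_graph(nodes, "yolov10n", nc, check_res(resolution))
}

#' Build the lightweight onboard variants (F-YOLOv10 and FF-YOLOv10)
#'
#' `build_f_yolov10()` replaces every C2f stage of the baseline with the
#' C2f-Faster block (FasterNet bottlenecks with a 1/4-prefix partial
#' convolution). `build_ff_yolov10()` additionally replaces the SPPF position
#' with a focal modulation block (2 focal levels, depthwise kernels 3 and 5),
#' yielding the full onboard model.
#'
#' @inheritParams build_yolov10n
#' @return a [model_graph()].
#' @export
build_ff_yolov10 <- function(nc = 1L, resolution = 480L, head = c("deploy", "full")) {
  head <- match.arg(head)
  nodes <- v10_nodes(as.integer(nc), c2f_kind = "c2f_faster", tail_kind = "focal")
  nodes[[24]]$args$dual <- head == "full"
  model_graph(nodes, "ff_yolov10", nc, check_res(resolution))
}

#' @rdname build_ff_yolov10
#' @export
build_f_yolov10 <- function(nc = 1L, resolution = 480L, head = c("deploy", "full")) {
  head <- match.arg(head)
  nodes <- v10_nodes(as.integer(nc), c2f_kind = "c2f_faster", tail_kind = "sppf")
  nodes[[24]]$args$dual <- head == "full"
  model_graph(nodes, "f_yolov10", nc, check_res(resolution))
}

# backbone of the ground-station detector (nodes 1..51: P5 aggregate)
v7_backbone <- function(pconv_site = FALSE) {
  cv <- function(from, c1, c2, k = 1L, s = 1L) nd("conv", from, c1 = c1, c2 = c2, k = k, s = s)
  elan <- function(w) {  # emits 8 nodes: 2 entries, 4-chain, concat, out
    c(list(cv(-1, 2L * w, w), cv(-2, 2L * w, w)),
      lapply(1:4, function(i) cv(-1, w, w, 3L)),
      list(nd("concat", c(-1, -3, -5, -6)), cv(-1, 4L * w, 4L * w)))
  }
  mp2 <- function(cin, w) list(nd("maxpool", -1, k = 2L, s = 2L),
                               cv(-1, cin, w), cv(-3, cin, w), cv(-1, w, w, 3L, 2L),
                               nd("concat", c(-1, -3)))
  nodes <- c(list(cv(0, 3L, 32L, 3L), cv(-1, 32L, 64L, 3L, 2L),
                  cv(-1, 64L, 64L, 3L), cv(-1, 64L, 128L, 3L, 2L)),
             elan(64L),                              # 5..12  (P2 out = 12)
             mp2(256L, 128L),                        # 13..17
             elan(128L),                             # 18..25 (P3 out = 25)
             mp2(512L, 256L),                        # 26..30
             elan(256L),                             # 31..38 (P4 out = 38)
             mp2(1024L, 512L),                       # 39..43
             list(cv(-1, 1024L, 256L), cv(-2, 1024L, 256L)),
             lapply(1:4, function(i) cv(-1, 256L, 256L, 3L)),
             list(nd("concat", c(-1, -3, -5, -6)), cv(-1, 1024L, 1024L)))  # 51 P5
  if (pconv_site) {
    # module B: the first 3x3 CBS of the second branch of the first backbone
    # ELAN becomes a bias-free partial convolution; the processed prefix is
    # 1/4 of the ELAN's 256-channel aggregate width, i.e. all 64 branch
    # channels, so only the folded bias is dropped.
    nodes[[7]] <- nd("pconv", -1, c = 64L, cp = 64L, k = 3L)
  }
  nodes
}

elan_w <- function(cin, w) {  # neck ELAN-W: 8 nodes
  cv <- function(from, c1, c2, k = 1L, s = 1L) nd("conv", from, c1 = c1, c2 = c2, k = k, s = s)
  c(list(cv(-1, cin, w), cv(-2, cin, w), cv(-1, w, w %/% 2L, 3L)),
    lapply(1:3, function(i) cv(-1, w %/% 2L, w %/% 2L, 3L)),
    list(nd("concat", c(-1, -2, -3, -4, -5, -6)), cv(-1, 4L * w, w)))
}

#' Build the ground-station baseline detector (YOLOv7)
#'
#' Standard base-scale architecture in its published deployment
#' configuration: ELAN backbone, max-pooling downsampling blocks, SPPCSPC,
#' PAFPN neck with ELAN-W aggregation, reparameterized (fused) convolution
#' heads at three scales (strides 8/16/32).
#'
#' @inheritParams build_yolov10n
#' @return a [model_graph()].
#' @export
build_yolov7 <- function(nc = 1L, resolution = 480L) {
  stopifnot(nc >= 1L)
  cv <- function(from, c1, c2, k = 1L, s = 1L) nd("conv", from, c1 = c1, c2 = c2, k = k, s = s)
  nodes <- c(
    v7_backbone(),                                        # 1..51
    list(nd("sppcspc", -1, c1 = 1024L, c2 = 512L),        # 52
         cv(-1, 512L, 256L), nd("upsample", -1, scale = 2L),
         cv(38, 1024L, 256L), nd("concat", c(-1, -2))),   # 53..56
    elan_w(512L, 256L),                                   # 57..64 (P4 mid = 64)
    list(cv(-1, 256L, 128L), nd("upsample", -1, scale = 2L),
         cv(25, 512L, 128L), nd("concat", c(-1, -2))),    # 65..68
    elan_w(256L, 128L),                                   # 69..76 (P3 out = 76)
    list(nd("maxpool", -1, k = 2L, s = 2L),
         cv(-1, 128L, 128L), cv(-3, 128L, 128L), cv(-1, 128L, 128L, 3L, 2L),
         nd("concat", c(-1, -3, 64))),                    # 77..81
    elan_w(512L, 256L),                                   # 82..89 (P4 out = 89)
    list(nd("maxpool", -1, k = 2L, s = 2L),
         cv(-1, 256L, 256L), cv(-3, 256L, 256L), cv(-1, 256L, 256L, 3L, 2L),
         nd("concat", c(-1, -3, 52))),                    # 90..94
    elan_w(1024L, 512L),                                  # 95..102 (P5 out = 102)
    list(nd("repconv", 76, c1 = 128L, c2 = 256L),         # 103
         nd("repconv", 89, c1 = 256L, c2 = 512L),         # 104
         nd("repconv", 102, c1 = 512L, c2 = 1024L),       # 105
         nd("detect_v7", c(103, 104, 105), ch = c(256L, 512L, 1024L),
            nc = as.integer(nc), na = 3L, implicits = FALSE))
  )
  model_graph(nodes, "yolov7", nc, check_res(resolution))
}

#' Build the enhanced ground-station detector (YOLOv7+A, PP-YOLOv7)
#'
#' Adds the fourth, stride-4 small-target detection scale (module A): the
#' finest neck level is reduced and upsampled to 120x120 (at 480 input),
#' fused with the matching stride-4 backbone feature, aggregated by an
#' ELAN-W block, and returned to the bottom-up path through a max-pooling
#' transition, giving detection grids at strides 4/8/16/32. The four heads
#' use the reparameterized convolution design with implicit knowledge terms
#' (a learned per-channel additive prior on each head input and a
#' multiplicative prior on each output). With `with_pconv = TRUE` (module B,
#' the full PP-YOLOv7), the designated second-branch CBS convolution of the
#' first backbone ELAN is replaced by the bias-free partial convolution.
#'
#' @inheritParams build_yolov10n
#' @param with_pconv apply the partial-convolution ELAN-branch substitution
#'   (module B) in addition to the small-target layer.
#' @return a [model_graph()].
#' @export
build_pp_yolov7 <- function(nc = 1L, resolution = 480L, with_pconv = TRUE) {
  stopifnot(nc >= 1L)
  cv <- function(from, c1, c2, k = 1L, s = 1L) nd("conv", from, c1 = c1, c2 = c2, k = k, s = s)
  nodes <- c(
    v7_backbone(pconv_site = with_pconv),                 # 1..51
    list(nd("sppcspc", -1, c1 = 1024L, c2 = 512L),        # 52
         cv(-1, 512L, 256L), nd("upsample", -1, scale = 2L),
         cv(38, 1024L, 256L), nd("concat", c(-1, -2))),   # 53..56
    elan_w(512L, 256L),                                   # 57..64
    list(cv(-1, 256L, 128L), nd("upsample", -1, scale = 2L),
         cv(25, 512L, 128L), nd("concat", c(-1, -2))),    # 65..68
    elan_w(256L, 128L),                                   # 69..76 (P3 mid = 76)
    # ---- module A: small-target (P2) scale ----
    list(cv(-1, 128L, 64L), nd("upsample", -1, scale = 2L),    # 77, 78
         cv(12, 256L, 64L), nd("concat", c(-1, -2)),           # 79, 80
         cv(-1, 128L, 64L), cv(-2, 128L, 64L),                 # 81, 82
         cv(-1, 64L, 32L, 3L), cv(-1, 32L, 32L, 3L),           # 83, 84
         cv(-1, 32L, 32L, 3L), cv(-1, 32L, 32L, 3L),           # 85, 86
         nd("concat", c(-1, -2, -3, -4, -5, -6)),              # 87 (256)
         cv(-1, 256L, 64L),                                    # 88 P2 out
         nd("maxpool", -1, k = 2L, s = 2L),                    # 89
         cv(-1, 64L, 64L), cv(-3, 64L, 64L),                   # 90, 91
         cv(-1, 64L, 64L, 3L, 2L),                             # 92
         nd("concat", c(-1, -3, 76)),                          # 93 (256)
         cv(-1, 256L, 128L), cv(-2, 256L, 128L),               # 94, 95
         cv(-1, 128L, 64L, 3L), cv(-1, 64L, 64L, 3L),          # 96, 97
         cv(-1, 64L, 64L, 3L), cv(-1, 64L, 64L, 3L),           # 98, 99
         nd("concat", c(-1, -2, -3, -4, -5, -6)),              # 100 (512)
         cv(-1, 512L, 128L)),                                  # 101 P3 out
    list(nd("maxpool", -1, k = 2L, s = 2L),
         cv(-1, 128L, 128L), cv(-3, 128L, 128L), cv(-1, 128L, 128L, 3L, 2L),
         nd("concat", c(-1, -3, 64))),                         # 102..106
    elan_w(512L, 256L),                                        # 107..114 (P4 out)
    list(nd("maxpool", -1, k = 2L, s = 2L),
         cv(-1, 256L, 256L), cv(-3, 256L, 256L), cv(-1, 256L, 256L, 3L, 2L),
         nd("concat", c(-1, -3, 52))),                         # 115..119
    elan_w(1024L, 512L),                                       # 120..127 (P5 out)
    list(nd("repconv", 88, c1 = 64L, c2 = 128L),               # 128 P2 head
         nd("repconv", 101, c1 = 128L, c2 = 256L),             # 129
         nd("repconv", 114, c1 = 256L, c2 = 512L),             # 130
         nd("repconv", 127, c1 = 512L, c2 = 1024L),            # 131
         nd("detect_v7", c(128, 129, 130, 131),
            ch = c(128L, 256L, 512L, 1024L), nc = as.integer(nc), na = 3L,
            implicits = TRUE))
  )
  model_graph(nodes, if (with_pconv) "pp_yolov7" else "yolov7_a",
              nc, check_res(resolution))
}

#' @rdname build_pp_yolov7
#' @export
build_yolov7_a <- function(nc = 1L, resolution = 480L)
  build_pp_yolov7(nc, resolution, with_pconv = FALSE)

#' Build a detector graph by name
#'
#' @param model one of `"yolov10n"`, `"f_yolov10"`, `"ff_yolov10"`,
#'   `"yolov7"`, `"yolov7_a"`, `"pp_yolov7"`.
#' @inheritParams build_yolov10n
#' @return a [model_graph()].
#' @export
build_model <- function(model, nc = 1L, resolution = 480L) {
  switch(model,
         yolov10n = build_yolov10n(nc, resolution),
         f_yolov10 = build_f_yolov10(nc, resolution),
         ff_yolov10 = build_ff_yolov10(nc, resolution),
         yolov7 = build_yolov7(nc, resolution),
         yolov7_a = build_yolov7_a(nc, resolution),
         pp_yolov7 = build_pp_yolov7(nc, resolution),
         stop("unknown model: ", model, call. = FALSE))
}
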