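#' Detector model graphs
#'
#' A `model_graph` is a declarative, ordered list of layer nodes with explicit
#' from-indices (0 refers to the image input, negative indices are relative,
#' as in the YOLO configuration dialect). Graphs are buildable without
#' weights: parameter counts and output shapes are pure functions of the
#' specification. [init_weights()] attaches deterministic random weights for
#' forward execution.
#'
#' @param nodes list of nodes (`list(kind =, from =, args =)`).
#' @param name model name.
#' @param nc number of classes.
#' @param resolution nominal input resolution (used for analytic
#'   multiply-accumulate counts; parameter counts are resolution-independent).
#' @return an object of class `model_graph`.
#' @export
model_graph <- function(nodes, name, nc, resolution = 480L) {
  for (i in seq_along(nodes)) {
    fr <- nodes[[i]]$from
    fr <- ifelse(fr < 0L, i + fr, fr)  # resolve relative indices
    if (any(fr < 0L | fr >= i))
      stop(sprintf("node %d has an invalid from-index (graph must be a DAG)", i),
           call. = FALSE)
    nodes[[i]]$from <- as.integer(fr)
  }
  structure(list(nodes = nodes, name = name, nc = as.integer(nc),
                 resolution = as.integer(resolution), weights = NULL),
            class = "model_graph")
}

nd <- function(.kind, .from, ...) list(kind = .kind, from = as.integer(.from),
                                       args = list(...))

#' Exact parameter accounting for a model graph
#'
#' Counts every stored scalar of the model, per layer and in total, under two
#' conventions: `train` (training graph: batch-norm affine terms counted,
#' reparameterizable branches unfused) and `deploy` (inference graph:
#' batch-norm folded into convolution biases, reparameterized convolutions
#' fused). `total` is the deploy count, the figure quoted for deployed model
#' sizes. An analytic multiply-accumulate count at the graph's nominal
#' resolution is included. Counts are deterministic and independent of input
#' data and resolution.
#'
#' @param graph a [model_graph()].
#' @return a `param_report`: list with `total`, `total_train`, `per_layer`
#'   data frame and `macs`.
#' @examples
#' g <- build_yolov10n(nc = 1)
#' count_parameters(g)$total
#' @export
count_parameters <- function(graph) {
  stopifnot(inherits(graph, "model_graph"))
  dep <- vapply(graph$nodes, node_count, numeric(1), mode = "deploy")
  trn <- vapply(graph$nodes, node_count, numeric(1), mode = "train")
  shapes <- graph_shapes(graph)
  macs <- vapply(seq_along(graph$nodes), function(i)
    node_macs(graph$nodes[[i]],
              lapply(graph$nodes[[i]]$from, function(f)
                if (f == 0L) c(graph$resolution, graph$resolution, 3L) else shapes[[f]])),
    numeric(1))
  per <- data.frame(layer = seq_along(graph$nodes),
                    kind = vapply(graph$nodes, `[[`, "", "kind"),
                    params = dep, params_train = trn, macs = macs)
  structure(list(model = graph$name, total = sum(dep), total_train = sum(trn),
                 per_layer = per, macs = sum(macs)),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("<param_report> %s\n", x$model))
  cat(sprintf("  parameters (deploy): %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  parameters (train) : %s\n", format(x$total_train, big.mark = ",")))
  cat(sprintf("  analytic MACs      : %.2f G\n", x$macs / 1e9))
  invisible(x)
}

# spatial shapes of every node output at the nominal resolution
graph_shapes <- function(graph, resolution = graph$resolution) {
  shapes <- vector("list", length(graph$nodes))
  inp <- c(resolution, resolution, 3L)
  for (i in seq_along(graph$nodes)) {
    node <- graph$nodes[[i]]
    ins <- lapply(node$from, function(f) {
      s <- if (f == 0L) inp else shapes[[f]]
      if (is.list(s)) stop("detection outputs cannot feed further layers", call. = FALSE)
      s
    })
    shapes[[i]] <- node_out_shape(node, ins)
  }
  shapes
}

# analytic multiply-accumulates: weight-elements x output spatial positions for
# every convolution in the node (attention terms ignored: they are not MACs of
# a convolution and are negligible at the backbone tail resolution)
node_macs <- function(node, ins) {
  hw <- prod(node_spatial(node, ins))
  node_count(node, mode = "deploy") * hw  # bias adds are counted with weights
}

node_spatial <- function(node, ins) {
  s <- node_out_shape(node, ins)
  if (is.list(s)) s <- s[[1]]
  s[1:2]
}

#' Attach deterministic weights to a graph
#'
#' Initializes deploy-form weights (fused convolution + bias) for every layer
#' from R's RNG; with a fixed seed the weights, and therefore every forward
#' pass, are reproducible.
#'
#' @param graph a [model_graph()].
#' @param seed integer seed.
#' @return the graph with a `weights` list attached.
#' @export
init_weights <- function(graph, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  graph$weights <- lapply(graph$nodes, node_init)
  graph
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run a model graph forward
#'
#' Executes the DAG on an `h x w x 3` image array. The graph must carry
#' weights (see [init_weights()]). Returns the output of the final node: for
#' detection heads, a list of per-scale prediction maps.
#'
#' @param graph a weighted [model_graph()].
#' @param x input image array (`h x w x 3`, values any finite range).
#' @return output of the last node.
#' @export
forward <- function(graph, x) {
  stopifnot(inherits(graph, "model_graph"))
  if (is.null(graph$weights))
    stop("graph has no weights; call init_weights() first", call. = FALSE)
  outs <- vector("list", length(graph$nodes))
  keep <- needed_until(graph)
  for (i in seq_along(graph$nodes)) {
    node <- graph$nodes[[i]]
    ins <- lapply(node$from, function(f) if (f == 0L) x else outs[[f]])
    outs[[i]] <- node_forward(node, ins, graph$weights[[i]])
    drop <- which(keep < i + 1L & !vapply(outs, is.null, TRUE))
    for (j in drop) if (j < i) outs[j] <- list(NULL)
  }
  outs[[length(outs)]]
}

needed_until <- function(graph) {
  last <- seq_along(graph$nodes)
  for (i in seq_along(graph$nodes))
    for (f in graph$nodes[[i]]$from) if (f > 0L) last[f] <- max(last[f], i)
  last
}

#' Serialize and restore model graphs
#'
#' Writes the declarative layer list (kind, from-indices, arguments) to a
#' plain-text YAML file and rebuilds an identical graph from it; a rebuilt
#' graph yields an identical parameter report.
#'
#' @param graph a [model_graph()].
#' @param path file path.
#' @return `read_model_spec()` returns a `model_graph` (without weights).
#' @export
write_model_spec <- function(graph, path) {
  spec <- list(name = graph$name, nc = graph$nc, resolution = graph$resolution,
               nodes = lapply(graph$nodes, function(n)
                 list(kind = n$kind, from = n$from, args = n$args)))
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  nodes <- lapply(spec$nodes, function(n) {
    n$args <- lapply(n$args, function(a) if (is.numeric(a)) as.integer(a) else a)
    list(kind = n$kind, from = as.integer(n$from), args = n$args)
  })
  model_graph(nodes, spec$name, spec$nc, spec$resolution)
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph> %s: %d layers, nc = %d, input %dx%d\n",
              x$name, length(x$nodes), x$nc, x$resolution, x$resolution))
  invisible(x)
}
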