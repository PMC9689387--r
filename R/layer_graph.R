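#' Layer graphs: ordered network specifications
#'
#' A `layer_graph` is a directed acyclic graph of named nodes describing a
#' small convolutional network: `input`, `conv2d`, `linear`, `batchnorm`,
#' `relu`, nearest-neighbour `upsample`, elementwise `add` and spatial
#' `saliency` masking. It is the common currency of the package: the same
#' graph is executed as a conventional ReLU network, folded
#' ([fold_batchnorm()]), converted to a rate-coded spiking network
#' ([convert_to_snn()]), counted for multiply-accumulates ([count_flops()]),
#' and serialised to the JSON network container
#' ([write_network()]/[read_network()]).
#'
#' Nodes must be supplied in topological order (each node's inputs appear
#' earlier); there must be exactly one `input` node, and every `batchnorm`
#' must immediately follow a `conv2d` or `linear` node.
#'
#' @param nodes list of nodes built with the `node_*()` constructors.
#' @param outputs character vector of node ids treated as network outputs;
#'   defaults to all nodes with no consumers.
#' @return An object of class `layer_graph`.
#' @seealso [node_conv2d()], [graph_forward()]
#' @export
layer_graph <- function(nodes, outputs = NULL) {
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  names(nodes) <- ids
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  if (sum(kinds == "input") != 1L) {
    stop("a layer_graph needs exactly one input node", call. = FALSE)
  }
  seen <- character(0)
  consumed <- character(0)
  for (nd in nodes) {
    miss <- setdiff(nd$inputs, seen)
    if (length(miss) > 0) {
      stop(sprintf("node '%s' refers to undefined/later node(s): %s",
                   nd$id, paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (nd$kind == "batchnorm") {
      prev <- nodes[[nd$inputs[1]]]
      if (!prev$kind %in% c("conv2d", "linear")) {
        stop(sprintf("batchnorm '%s' must follow a conv2d or linear node",
                     nd$id), call. = FALSE)
      }
      if (any(nd$sigma <= 0)) {
        stop(sprintf("batchnorm '%s' has non-positive sigma", nd$id),
             call. = FALSE)
      }
    }
    consumed <- c(consumed, nd$inputs)
    seen <- c(seen, nd$id)
  }
  if (is.null(outputs)) outputs <- setdiff(ids, unique(consumed))
  if (!all(outputs %in% ids)) stop("unknown output id", call. = FALSE)
  structure(list(nodes = nodes, outputs = outputs), class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat(sprintf("layer_graph: %d nodes (%s)\n", length(x$nodes),
              paste(sprintf("%s:%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Node constructors for [layer_graph()]
#'
#' @param id unique node name.
#' @param input,inputs id(s) of upstream node(s).
#' @param shape input image shape `c(h, w, channels)`.
#' @param w weights: a `(kh, kw, in_channels, out_channels)` array for
#'   `conv2d`, an `(in, out)` matrix for `linear`.
#' @param b bias vector, one per output channel/unit.
#' @param stride,pad conv stride and symmetric zero padding (pixels).
#' @param gamma,beta,mu,sigma batch-norm scale, shift, running mean and
#'   running standard deviation (all per channel; `sigma > 0`).
#' @param factor nearest-neighbour upsampling factor.
#' @param channel_gate logical; also apply the per-channel global-average
#'   gate in a `saliency` node (spatial sum-mask only by default).
#' @return A node list suitable for [layer_graph()].
#' @name graph_nodes
NULL

#' @rdname graph_nodes
#' @export
node_input <- function(id, shape) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  list(id = id, kind = "input", inputs = character(0),
       shape = as.integer(shape))
}

#' @rdname graph_nodes
#' @export
node_conv2d <- function(id, input, w, b = NULL, stride = 1L, pad = 0L) {
  stopifnot(length(dim(w)) == 4L)
  if (is.null(b)) b <- numeric(dim(w)[4])
  stopifnot(length(b) == dim(w)[4], stride >= 1L, pad >= 0L)
  list(id = id, kind = "conv2d", inputs = input, w = w, b = as.numeric(b),
       stride = as.integer(stride), pad = as.integer(pad))
}

#' @rdname graph_nodes
#' @export
node_linear <- function(id, input, w, b = NULL) {
  w <- as.matrix(w)
  if (is.null(b)) b <- numeric(ncol(w))
  stopifnot(length(b) == ncol(w))
  list(id = id, kind = "linear", inputs = input, w = w, b = as.numeric(b))
}

#' @rdname graph_nodes
#' @export
node_batchnorm <- function(id, input, gamma, beta, mu, sigma) {
  stopifnot(length(gamma) == length(beta), length(mu) == length(sigma),
            length(gamma) == length(mu))
  list(id = id, kind = "batchnorm", inputs = input,
       gamma = as.numeric(gamma), beta = as.numeric(beta),
       mu = as.numeric(mu), sigma = as.numeric(sigma))
}

#' @rdname graph_nodes
#' @export
node_relu <- function(id, input) {
  list(id = id, kind = "relu", inputs = input)
}

#' @rdname graph_nodes
#' @export
node_upsample <- function(id, input, factor = 2L) {
  stopifnot(factor >= 1L)
  list(id = id, kind = "upsample", inputs = input, factor = as.integer(factor))
}

#' @rdname graph_nodes
#' @export
node_add <- function(id, inputs) {
  stopifnot(length(inputs) >= 2L)
  list(id = id, kind = "add", inputs = inputs)
}

#' @rdname graph_nodes
#' @export
node_saliency <- function(id, input, channel_gate = FALSE) {
  list(id = id, kind = "saliency", inputs = input,
       channel_gate = isTRUE(channel_gate))
}

graph_input_id <- function(graph) {
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  names(graph$nodes)[kinds == "input"]
}

#' Propagate tensor shapes through a layer graph
#'
#' @param graph a [layer_graph()].
#' @return Named list mapping node id to its output shape `c(h, w, c)` (or
#'   feature count for `linear` outputs).
#' @export
infer_shapes <- function(graph) {
  shp <- list()
  for (nd in graph$nodes) {
    shp[[nd$id]] <- switch(
      nd$kind,
      input = nd$shape,
      conv2d = {
        s <- shp[[nd$inputs[1]]]
        dw <- dim(nd$w)
        if (s[3] != dw[3]) {
          stop(sprintf("node '%s': input has %d channels, weights expect %d",
                       nd$id, s[3], dw[3]), call. = FALSE)
        }
        c(conv_out_dim(s[1], dw[1], nd$stride, nd$pad),
          conv_out_dim(s[2], dw[2], nd$stride, nd$pad), dw[4])
      },
      linear = {
        s <- shp[[nd$inputs[1]]]
        if (prod(s) != nrow(nd$w)) {
          stop(sprintf("node '%s': linear expects %d inputs, got %d",
                       nd$id, nrow(nd$w), prod(s)), call. = FALSE)
        }
        ncol(nd$w)
      },
      batchnorm = , relu = , saliency = shp[[nd$inputs[1]]],
      upsample = {
        s <- shp[[nd$inputs[1]]]
        c(s[1] * nd$factor, s[2] * nd$factor, s[3])
      },
      add = {
        ss <- shp[nd$inputs]
        if (!all(vapply(ss, function(z) identical(z, ss[[1]]), logical(1)))) {
          stop(sprintf("node '%s': add inputs disagree in shape", nd$id),
               call. = FALSE)
        }
        ss[[1]]
      },
      stop(sprintf("unknown node kind '%s'", nd$kind), call. = FALSE)
    )
  }
  shp
}

saliency_mask_t4 <- function(x) {
  d <- dim(x)
  mask <- array(0, c(d[1], d[2], 1L, d[4]))
  for (b in seq_len(d[4])) {
    s <- apply(x[, , , b, drop = FALSE], c(1, 2), sum)
    mn <- min(s); mx <- max(s)
    mask[, , 1L, b] <- if (mx > mn) (s - mn) / (mx - mn) else 1
  }
  mask
}

channel_gate_t4 <- function(x) {
  d <- dim(x)
  g <- matrix(0, d[3], d[4])
  for (b in seq_len(d[4])) {
    a <- apply(x[, , , b, drop = FALSE], 3, mean)
    mx <- max(a)
    g[, b] <- if (mx > 0) a / mx else 1
  }
  g
}

eval_graph_node <- function(nd, ins, training = FALSE) {
  switch(
    nd$kind,
    conv2d = conv2d_forward(ins[[1]], nd$w, nd$b, nd$stride, nd$pad,
                            ix = nd$ix, keep_cols = training),
    linear = {
      x <- as_t4(ins[[1]])
      xm <- matrix(x, ncol = dim(x)[4])
      sweep(crossprod(nd$w, xm), 1L, nd$b, `+`)  # (out, N)
    },
    batchnorm = {
      x <- as_t4(ins[[1]])
      d <- dim(x)
      xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
      ym <- sweep(sweep(xm, 2L, nd$mu, `-`), 2L, nd$gamma / nd$sigma, `*`)
      ym <- sweep(ym, 2L, nd$beta, `+`)
      aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
    },
    relu = pmax(ins[[1]], 0),
    upsample = upsample_nearest(ins[[1]], nd$factor),
    add = Reduce(`+`, ins),
    saliency = apply_saliency_t4(ins[[1]], nd$channel_gate),
    stop(sprintf("cannot evaluate node kind '%s'", nd$kind), call. = FALSE)
  )
}

apply_saliency_t4 <- function(x, channel_gate = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  m <- saliency_mask_t4(x)
  y <- x
  for (b in seq_len(d[4])) {
    mb <- m[, , 1L, b]
    for (ch in seq_len(d[3])) y[, , ch, b] <- x[, , ch, b] * mb
  }
  if (channel_gate) {
    g <- channel_gate_t4(x)
    for (b in seq_len(d[4])) {
      for (ch in seq_len(d[3])) y[, , ch, b] <- y[, , ch, b] * g[ch, b]
    }
  }
  attr(y, "mask") <- m
  y
}

#' Run a layer graph forward
#'
#' Executes the graph on a batch of images. Activations are dense
#' throughout; this is the conventional (non-spiking) network evaluation.
#'
#' @param graph a [layer_graph()].
#' @param x input: `(h, w)` matrix, `(h, w, c)` array or `(h, w, c, n)`
#'   batch matching the graph's input shape.
#' @param all_nodes return every node's activation rather than just the
#'   graph outputs.
#' @return Named list of output tensors `(h, w, c, n)` (named by node id).
#' @export
graph_forward <- function(graph, x, all_nodes = FALSE) {
  stopifnot(inherits(graph, "layer_graph"))
  x <- as_t4(x)
  inp <- graph_input_id(graph)
  shp <- graph$nodes[[inp]]$shape
  if (!identical(dim(x)[1:3], shp)) {
    stop(sprintf("input is %s, graph expects %s",
                 paste(dim(x)[1:3], collapse = "x"),
                 paste(shp, collapse = "x")), call. = FALSE)
  }
  vals <- list()
  for (nd in graph$nodes) {
    vals[[nd$id]] <- if (nd$kind == "input") {
      x
    } else if (nd$kind == "saliency") {
      apply_saliency_t4(vals[[nd$inputs[1]]], nd$channel_gate)
    } else {
      eval_graph_node(nd, vals[nd$inputs])
    }
  }
  if (all_nodes) vals else vals[graph$outputs]
}

#' Read or write the JSON network container
#'
#' Networks are stored as a single JSON document: a node manifest carrying
#' layer kinds, geometry and flattened weight arrays (with their dims), plus
#' the output list. The format is plain text and round-trips exactly at
#' double precision.
#'
#' @param graph a [layer_graph()].
#' @param path file path of the container (`.json`).
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [layer_graph()].
#' @export
write_network <- function(graph, path) {
  stopifnot(inherits(graph, "layer_graph"))
  jsonlite::write_json(
    c(list(format = "spikelesion-network", version = 1L),
      serialize_graph(graph)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

serialize_graph <- function(graph) {
  ser <- lapply(graph$nodes, function(nd) {
    nd$ix <- NULL
    if (!is.null(nd$w)) {
      nd$w_dim <- dim(nd$w)
      nd$w <- as.vector(nd$w)
    }
    nd
  })
  list(nodes = unname(ser), outputs = graph$outputs)
}

deserialize_nodes <- function(raw_nodes) {
  lapply(raw_nodes, function(nd) {
    nd$inputs <- as.character(unlist(nd$inputs))
    if (!is.null(nd$w)) {
      w <- as.numeric(unlist(nd$w))
      dm <- as.integer(unlist(nd$w_dim))
      nd$w <- if (length(dm) == 2L) matrix(w, dm[1], dm[2]) else array(w, dm)
      nd$w_dim <- NULL
    }
    for (f in c("b", "gamma", "beta", "mu", "sigma", "var_run",
                "gains", "gain")) {
      if (!is.null(nd[[f]])) nd[[f]] <- as.numeric(unlist(nd[[f]]))
    }
    if (!is.null(nd$shape)) nd$shape <- as.integer(unlist(nd$shape))
    for (f in c("stride", "pad", "factor")) {
      if (!is.null(nd[[f]])) nd[[f]] <- as.integer(nd[[f]])
    }
    nd
  })
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "spikelesion-network")) {
    stop("not a spikelesion network container: ", path, call. = FALSE)
  }
  nodes <- deserialize_nodes(doc$nodes)
  layer_graph(nodes, outputs = as.character(unlist(doc$outputs)))
}
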