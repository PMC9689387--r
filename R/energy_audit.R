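#' Per-operation energy costs
#'
#' Published 45 nm CMOS estimates for a 32-bit multiply-accumulate (MAC)
#' and a 32-bit accumulate (AC): 4.6 / 0.9 pJ in floating point and
#' 3.2 / 0.1 pJ in integer arithmetic. A conventional network spends one MAC
#' per weight per output; a spiking network spends one AC per spike per
#' synapse.
#'
#' @param precision `"32-bit FL"` or `"32-bit INT"`.
#' @param mac_pj,ac_pj override the per-operation costs (picojoules).
#' @return An object of class `op_costs`.
#' @export
op_costs <- function(precision = c("32-bit FL", "32-bit INT"),
                     mac_pj = NULL, ac_pj = NULL) {
  precision <- match.arg(precision)
  defaults <- list("32-bit FL" = c(mac = 4.6, ac = 0.9),
                   "32-bit INT" = c(mac = 3.2, ac = 0.1))[[precision]]
  mac_pj <- if (is.null(mac_pj)) defaults[["mac"]] else mac_pj
  ac_pj <- if (is.null(ac_pj)) defaults[["ac"]] else ac_pj
  if (mac_pj <= 0 || ac_pj <= 0) stop("costs must be positive", call. = FALSE)
  structure(list(mac_pj = mac_pj, ac_pj = ac_pj, precision = precision),
            class = "op_costs")
}

#' Count multiply-accumulates in a layer graph
#'
#' One MAC per multiply-add pair: a convolution costs
#' `out_h * out_w * out_c * (kh * kw * in_c)` MACs, a linear layer
#' `in * out`. Bias additions, elementwise adds and upsampling copies are
#' tallied separately (`other_ops`) and excluded from the MAC total.
#'
#' @param graph a [layer_graph()].
#' @return A list of class `flop_count`: `macs` total, `other_ops` total,
#'   `per_layer` data.frame (`layer`, `kind`, `macs`, `other_ops`).
#' @export
count_flops <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  shp <- infer_shapes(graph)
  rows <- list()
  for (nd in graph$nodes) {
    macs <- 0; other <- 0
    if (nd$kind == "conv2d") {
      s <- shp[[nd$id]]
      dw <- dim(nd$w)
      macs <- prod(s) * dw[1] * dw[2] * dw[3]
      other <- prod(s)  # bias adds
    } else if (nd$kind == "linear") {
      macs <- prod(dim(nd$w))
      other <- ncol(nd$w)
    } else if (nd$kind == "add") {
      other <- prod(shp[[nd$id]]) * (length(nd$inputs) - 1L)
    } else if (nd$kind == "upsample") {
      other <- prod(shp[[nd$id]])
    } else if (nd$kind == "batchnorm") {
      other <- 2 * prod(shp[[nd$id]])
    }
    if (nd$kind != "input") {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = nd$id, kind = nd$kind, macs = macs, other_ops = other)
    }
  }
  per_layer <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(layer = character(0), kind = character(0),
               macs = numeric(0), other_ops = numeric(0))
  structure(list(macs = sum(per_layer$macs),
                 other_ops = sum(per_layer$other_ops),
                 per_layer = per_layer),
            class = "flop_count")
}

#' Synapse fan-out of every IF layer in a spiking graph
#'
#' For each IF (relu) node, counts the number of outgoing synapses of every
#' neuron: the number of times the downstream convolution or linear layers
#' read it (exact, including border effects), summed over all direct
#' consumers inside the spiking region. Elementwise pass-through consumers
#' (add, upsample) forward the fan-out of their own consumers.
#'
#' @param snn a [convert_to_snn()] result.
#' @return Named list (per IF layer) of fan-out arrays matching the layer
#'   shape.
#' @keywords internal
snn_fanout <- function(snn) {
  base <- layer_graph(unname(lapply(snn$nodes, function(nd) {
    nd$gains <- NULL; nd$gain <- NULL; nd$ix <- NULL; nd
  })), outputs = snn$outputs)
  shp <- infer_shapes(base)
  ids <- names(snn$nodes)
  kinds <- vapply(snn$nodes, `[[`, character(1), "kind")
  consumers <- lapply(ids, function(i) {
    ids[vapply(snn$nodes, function(nd) i %in% nd$inputs, logical(1))]
  })
  names(consumers) <- ids
  # fan-out of node i's output tensor, resolved lazily
  memo <- new.env(parent = emptyenv())
  fanout_of <- function(i) {
    if (exists(i, envir = memo, inherits = FALSE)) return(memo[[i]])
    s <- shp[[i]]
    fo <- array(0, s)
    for (ci in consumers[[i]]) {
      nd <- snn$nodes[[ci]]
      if (nd$kind %in% c("conv2d")) {
        dw <- dim(nd$w)
        ix <- conv_im2col_index(s[1], s[2], s[3], dw[1], dw[2],
                                nd$stride, nd$pad)
        reads <- tabulate(as.vector(ix$idx), nbins = ix$hp * ix$wp * ix$c)
        reads <- array(reads, c(ix$hp, ix$wp, ix$c))
        p <- ix$pad
        reads <- if (p > 0) reads[p + seq_len(s[1]), p + seq_len(s[2]), ,
                                  drop = FALSE] else reads
        fo <- fo + reads * dw[4]
      } else if (nd$kind == "linear") {
        fo <- fo + ncol(nd$w)
      } else if (nd$kind == "add") {
        fo <- fo + fanout_of(ci)
      } else if (nd$kind == "upsample") {
        down <- fanout_of(ci)
        f <- nd$factor
        agg <- array(0, s)
        for (a in seq_len(f)) for (b in seq_len(f)) {
          agg <- agg + down[seq(a, by = f, length.out = s[1]),
                            seq(b, by = f, length.out = s[2]), , drop = FALSE]
        }
        fo <- fo + agg
      } else if (nd$kind %in% c("relu", "saliency")) {
        fo <- fo + fanout_of(ci)
      }
    }
    memo[[i]] <- fo
    fo
  }
  out <- list()
  for (i in ids[kinds == "relu"]) out[[i]] <- fanout_of(i)
  out
}

#' Count synaptic operations of a spiking simulation
#'
#' An event-driven spiking network performs one accumulate per spike per
#' outgoing synapse, so the total is
#' \eqn{\sum_{\mathrm{neurons}} \mathrm{spikes} \times \mathrm{fan\,out}}.
#' Fan-outs are derived exactly from the graph geometry (see
#' [snn_fanout()]); the simulation record supplies per-neuron spike counts.
#'
#' @param sim an `snn_sim` record from [simulate_rates()].
#' @param snn the [convert_to_snn()] network that produced it.
#' @return Total synaptic operation (AC) count.
#' @export
count_synaptic_ops <- function(sim, snn) {
  stopifnot(inherits(sim, "snn_sim"), inherits(snn, "spiking_graph"))
  if (is.null(sim$counts) || length(sim$counts) == 0) {
    stop("simulation record carries no spike counts", call. = FALSE)
  }
  fo <- snn_fanout(snn)
  if (!all(names(sim$counts) %in% names(fo))) {
    stop("simulation record does not match the network's IF layers",
         call. = FALSE)
  }
  total <- 0
  for (i in names(sim$counts)) {
    total <- total + sum(as.vector(sim$counts[[i]]) * as.vector(fo[[i]]))
  }
  total
}

#' Energy of an operation count
#'
#' @param count number of operations (MACs or ACs), non-negative.
#' @param costs an [op_costs()] object.
#' @param mode `"MAC"` or `"AC"`: which per-operation cost applies.
#' @return Energy in joules: `count * cost_pj * 1e-12`.
#' @examples
#' energy_joules(6.97e9, op_costs("32-bit FL"), "MAC")  # ~0.032 J
#' @export
energy_joules <- function(count, costs = op_costs(), mode = c("MAC", "AC")) {
  mode <- match.arg(mode)
  stopifnot(inherits(costs, "op_costs"))
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  pj <- if (mode == "MAC") costs$mac_pj else costs$ac_pj
  count * pj * 1e-12
}

#' Full energy report for a network
#'
#' Combines FLOP counting (conventional execution, MAC costs) and, when a
#' simulation record is supplied, synaptic-operation counting (spiking
#' execution, AC costs) into a single comparison table.
#'
#' @param graph a [layer_graph()] (the conventional network).
#' @param costs an [op_costs()] object.
#' @param snn,sim optional [convert_to_snn()] network and
#'   [simulate_rates()] record for the spiking side.
#' @return A list of class `energy_report` with a `table` data.frame
#'   (`model`, `calculation_form`, `ops`, `op_kind`, `energy_J`) and the
#'   underlying counts.
#' @export
energy_report <- function(graph, costs = op_costs(), snn = NULL, sim = NULL) {
  fl <- count_flops(graph)
  rows <- data.frame(
    model = "ANN", calculation_form = costs$precision,
    ops = fl$macs, op_kind = "MAC",
    energy_J = energy_joules(fl$macs, costs, "MAC"))
  acs <- NULL
  if (!is.null(snn) && !is.null(sim)) {
    acs <- count_synaptic_ops(sim, snn)
    rows <- rbind(rows, data.frame(
      model = "SNN", calculation_form = costs$precision,
      ops = acs, op_kind = "AC",
      energy_J = energy_joules(acs, costs, "AC")))
  }
  structure(list(table = rows, macs = fl$macs, acs = acs,
                 per_layer = fl$per_layer, costs = costs),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("Energy report\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
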