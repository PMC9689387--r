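# Shared fixtures: tiny graphs and oracles used across test files.

# fine-step explicit Euler of the leaky membrane ODE, independent of the
# package's simulator (plain loop, its own step size)
euler_membrane_oracle <- function(t_end, ri0, tau, dt = 1e-4, v_rest = 0) {
  n <- round(t_end / dt)
  v <- v_rest
  for (i in seq_len(n)) v <- v + dt / tau * (-(v - v_rest) + ri0)
  v
}

# bisection on the charging curve for the first threshold crossing
bisect_spike_oracle <- function(ri0, v_th, tau, hi = 1e4) {
  f <- function(t) ri0 * (1 - exp(-t / tau)) - v_th
  if (f(hi) < 0) return(NA_real_)
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# random conv -> bn chains for folding equivalence checks
random_bn_graph <- function(n_layers = 3, size = 6, channels = 2) {
  nodes <- list(node_input("in", c(size, size, channels)))
  prev <- "in"; cin <- channels
  for (l in seq_len(n_layers)) {
    cout <- sample(1:4, 1)
    cid <- paste0("conv", l)
    nodes[[length(nodes) + 1]] <- node_conv2d(
      cid, prev, array(stats::rnorm(3 * 3 * cin * cout), c(3, 3, cin, cout)),
      b = stats::rnorm(cout), stride = 1L, pad = 1L)
    bid <- paste0("bn", l)
    nodes[[length(nodes) + 1]] <- node_batchnorm(
      bid, cid, gamma = stats::runif(cout, 0.5, 2),
      beta = stats::rnorm(cout), mu = stats::rnorm(cout),
      sigma = stats::runif(cout, 0.5, 2))
    rid <- paste0("relu", l)
    nodes[[length(nodes) + 1]] <- node_relu(rid, bid)
    prev <- rid; cin <- cout
  }
  layer_graph(nodes)
}

# one-IF-unit graph whose single weight is 1 (identity drive)
unit_if_graph <- function() {
  layer_graph(list(
    node_input("in", c(1, 1, 1)),
    node_conv2d("c", "in", array(1, c(1, 1, 1, 1))),
    node_relu("r", "c")))
}

# calibration batch spanning [0, 1] so the unit graph keeps scale 1
unit_calibration <- function() array(seq(0, 1, length.out = 16), c(1, 1, 1, 16))

tiny_dataset <- function(n = 6, seed = 42, size = 96) {
  generate_dataset(n, size = size, seed = seed)
}

as_t4_test <- function(x) array(x, c(dim(x)[1], dim(x)[2], 1, 1))

empty_boxes_test <- function() {
  data.frame(class = character(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0))
}

# exhaustive best assignment of detections to ground truths
brute_force_tp <- function(det, gt, thr = 0.5) {
  nd <- nrow(det)
  ord <- order(det$confidence, decreasing = TRUE)
  # replicate greedy semantics by trying all GT permutations and keeping
  # the assignment greedy matching would find: each detection in turn takes
  # the best-IoU remaining GT above threshold
  used <- logical(nrow(gt))
  tp <- logical(nd)
  for (k in seq_len(nd)) {
    d <- det[ord[k], ]
    ious <- vapply(seq_len(nrow(gt)), function(j) {
      if (used[j]) return(-1)
      box_iou(c(d$x_min, d$y_min, d$x_max, d$y_max),
              c(gt$x_min[j], gt$y_min[j], gt$x_max[j], gt$y_max[j]))
    }, numeric(1))
    j <- which.max(ious)
    if (length(j) == 1 && ious[j] >= thr) {
      tp[k] <- TRUE
      used[j] <- TRUE
    }
  }
  tp
}

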