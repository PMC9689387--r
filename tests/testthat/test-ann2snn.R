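test_that("batch-norm folding substitutes the closed-form parameters", {
  g <- layer_graph(list(
    node_input("in", c(4, 4, 1)),
    node_conv2d("c", "in", array(1, c(1, 1, 1, 1)), b = 0),
    node_batchnorm("bn", "c", gamma = 1, beta = 0, mu = 0, sigma = 1)))
  f <- fold_batchnorm(g)
  expect_equal(as.vector(f$nodes$c$w), 1)   # identity normalization
  expect_equal(f$nodes$c$b, 0)

  g2 <- layer_graph(list(
    node_input("in", c(4, 4, 1)),
    node_conv2d("c", "in", array(1, c(1, 1, 1, 1)), b = 0),
    node_batchnorm("bn", "c", gamma = 2, beta = 3, mu = 1, sigma = 4)))
  f2 <- fold_batchnorm(g2)
  expect_equal(as.vector(f2$nodes$c$w), 0.5)
  expect_equal(f2$nodes$c$b, 2.5)
  expect_false("bn" %in% names(f2$nodes))
})

test_that("folded graphs reproduce the conv-then-normalize composition", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_bn_graph(n_layers = 3)
    f <- fold_batchnorm(g)
    expect_false(any(vapply(f$nodes, `[[`, character(1), "kind") == "batchnorm"))
    for (k in 1:5) {
      x <- array(stats::rnorm(6 * 6 * 2), c(6, 6, 2))
      ya <- graph_forward(g, x)[[1]]
      yb <- graph_forward(f, x)[[1]]
      expect_lt(max(abs(ya - yb)), 1e-5)
    }
  }
})

test_that("folding is idempotent and rejects detached normalization", {
  set.seed(1)
  g <- random_bn_graph()
  f1 <- fold_batchnorm(g)
  f2 <- fold_batchnorm(f1)
  expect_equal(f1$nodes, f2$nodes)
  expect_error(layer_graph(list(
    node_input("in", c(2, 2, 1)),
    node_relu("r", "in"),
    node_batchnorm("bn", "r", 1, 0, 0, 1))), "must follow")
  expect_error(layer_graph(list(
    node_input("in", c(2, 2, 1)),
    node_conv2d("c", "in", array(1, c(1, 1, 1, 1))),
    node_batchnorm("bn", "c", 1, 0, 0, -1))), "sigma")
})

test_that("a single IF unit rate-codes its drive within 1/T", {
  # hand-enumerated: z = 0.3, T = 10 gives spikes at steps 4, 7, 10
  expect_equal(if_rate(0.3, 10), 0.3)
  expect_equal(if_rate(1, 5), 1)    # fires every step
  expect_equal(if_rate(0, 100), 0)
  for (tt in c(1, 7, 10, 100, 1000)) {
    x <- seq(0, 1, by = 0.1)
    f <- if_rate(x, tt)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(abs(f - x) <= 1 / tt + 1e-12))
  }
})

test_that("conversion of a single-unit graph reproduces rate coding", {
  snn <- convert_to_snn(unit_if_graph(),
                        rate_code_config(timesteps = 100, norm_percentile = 1),
                        unit_calibration())
  sim <- simulate_rates(snn, array(0.5, c(1, 1, 1)))
  expect_equal(as.vector(sim$rates[["r"]]), 0.5, tolerance = 1e-2)
  # negative drive never fires
  g <- layer_graph(list(
    node_input("in", c(1, 1, 1)),
    node_conv2d("c", "in", array(-1, c(1, 1, 1, 1))),
    node_relu("r", "c")))
  snn2 <- convert_to_snn(g, rate_code_config(timesteps = 50), unit_calibration())
  sim2 <- simulate_rates(snn2, array(0.8, c(1, 1, 1)))
  expect_equal(as.vector(sim2$rates[["r"]]), 0)
  expect_equal(sum(sim2$counts[["r"]]), 0)
})

test_that("graphs without ReLU convert to numerically identical forward passes", {
  set.seed(3)
  g <- layer_graph(list(
    node_input("in", c(4, 4, 1)),
    node_conv2d("c1", "in", array(stats::rnorm(9), c(3, 3, 1, 1)),
                b = 0.2, stride = 1L, pad = 1L)))
  x <- matrix(stats::runif(16), 4, 4)
  snn <- convert_to_snn(g, rate_code_config(timesteps = 64), as_t4_test(x))
  sim <- simulate_rates(snn, x)
  ya <- graph_forward(g, x)[[1]]
  expect_equal(sim$outputs[[1]], ya, tolerance = 1e-10)
})

test_that("equivalence audit obeys the single-layer residual bound", {
  snn <- convert_to_snn(unit_if_graph(),
                        rate_code_config(timesteps = 1000, norm_percentile = 1),
                        unit_calibration())
  inputs <- array(seq(0, 1, by = 0.25), c(1, 1, 1, 5))
  rep <- equivalence_audit(unit_if_graph(), snn, inputs, t_list = c(10, 100, 1000))
  for (tt in c(10, 100, 1000)) {
    expect_lte(max(rep$max_abs_err[rep$T == tt]), 1 / tt + 1e-12)
  }
  # zero input gives zero error
  rep0 <- equivalence_audit(unit_if_graph(), snn,
                            array(0, c(1, 1, 1, 1)), t_list = 16)
  expect_equal(rep0$max_abs_err, 0)
})

test_that("deep-net audit error shrinks with longer simulation", {
  set.seed(11)
  g <- random_bn_graph(n_layers = 3, size = 6, channels = 2)
  calib <- array(stats::runif(6 * 6 * 2 * 6), c(6, 6, 2, 6))
  snn <- convert_to_snn(g, rate_code_config(timesteps = 64), calib)
  x <- array(stats::runif(6 * 6 * 2), c(6, 6, 2, 1))
  rep <- equivalence_audit(g, snn, x, t_list = c(64, 1024))
  m64 <- mean(rep$mean_abs_err[rep$T == 64])
  m1024 <- mean(rep$mean_abs_err[rep$T == 1024])
  expect_lt(m1024, m64)
  expect_true(all(rep$max_abs_err >= 0))
})

test_that("rates stay in [0, 1] and shapes are preserved everywhere", {
  set.seed(5)
  g <- random_bn_graph(n_layers = 2, size = 8, channels = 1)
  calib <- array(stats::runif(8 * 8 * 4), c(8, 8, 1, 4))
  snn <- convert_to_snn(g, rate_code_config(timesteps = 32), calib)
  sim <- simulate_rates(snn, calib[, , , 1, drop = FALSE])
  acts <- graph_forward(g, calib[, , , 1, drop = FALSE], all_nodes = TRUE)
  for (i in names(sim$rates)) {
    expect_true(all(sim$rates[[i]] >= 0 & sim$rates[[i]] <= 1))
    expect_equal(dim(sim$rates[[i]]), dim(acts[[i]]))
  }
})

test_that("spiking network containers round-trip", {
  snn <- convert_to_snn(unit_if_graph(), rate_code_config(timesteps = 40),
                        unit_calibration())
  path <- withr::local_tempfile(fileext = ".json")
  write_snn(snn, path)
  back <- read_snn(path)
  expect_equal(back$scales, snn$scales, tolerance = 1e-12)
  sim_a <- simulate_rates(snn, array(0.4, c(1, 1, 1)))
  sim_b <- simulate_rates(back, array(0.4, c(1, 1, 1)))
  expect_equal(sim_a$rates, sim_b$rates)
})
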