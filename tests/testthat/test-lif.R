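test_that("parameter validation enforces the model invariants", {
  expect_s3_class(lif_params(), "lif_params")
  expect_error(lif_params(tau = -1), "tau")
  expect_error(lif_params(dt = 2), "tau/10")
  expect_error(lif_params(v_th = -1), "v_th")
  expect_error(lif_params(v_reset = 2), "v_reset")
})

test_that("closed-form membrane matches a fine-step Euler oracle", {
  p <- lif_params()
  # zero drive stays at rest
  expect_equal(membrane_closed_form(c(0, 5, 50), 0, p), c(0, 0, 0))
  # R*I0 = 2 mV reaches threshold (1 mV) at t = tau*ln 2
  expect_equal(membrane_closed_form(10 * log(2), 2, p), 1.0, tolerance = 1e-12)
  expect_equal(membrane_closed_form(10 * log(2), 2, p),
               euler_membrane_oracle(10 * log(2), 2, tau = 10),
               tolerance = 1e-4)
  # asymptote R*I0
  expect_equal(membrane_closed_form(100 * 10, 2, p), 2.0, tolerance = 1e-6)
  expect_error(membrane_closed_form(-1, 2, p), "non-negative")
})

test_that("closed-form interspike interval matches bisection on the charging curve", {
  p <- lif_params()
  expect_true(is.na(first_spike_interval(1.0, p)))   # drive exactly at threshold
  expect_true(is.na(first_spike_interval(0.5, p)))
  expect_equal(first_spike_interval(2, p), 10 * log(2), tolerance = 1e-12)
  for (ri0 in c(1.3, 2, 10)) {
    expect_equal(first_spike_interval(ri0, p),
                 bisect_spike_oracle(ri0, v_th = 1, tau = 10),
                 tolerance = 1e-8)
  }
  expect_equal(first_spike_interval(10, p), 10 * log(10 / 9), tolerance = 1e-12)
})

test_that("Euler simulation reproduces the closed forms and refractory bookkeeping", {
  p <- lif_params()
  flat <- simulate_constant_current(0, 100, p)
  expect_length(flat$spikes, 0)
  expect_true(all(flat$trace$voltage_mV == 0))

  sim <- simulate_constant_current(2, 100, p)
  dT <- first_spike_interval(2, p)
  expect_lt(abs(sim$spikes[1] - dT), 2 * p$dt)
  gaps <- diff(sim$spikes)
  expect_true(all(abs(gaps - (dT + p$tau_ref)) < 2 * p$dt))
  # no recorded sample exceeds threshold plus one Euler step of drive
  max_slope <- (2 - 0) / p$tau
  expect_true(all(sim$trace$voltage_mV <= p$v_th + max_slope * p$dt))
})

test_that("halving dt moves spike times by at most the previous step", {
  p1 <- lif_params(dt = 0.02)
  p2 <- lif_params(dt = 0.01)
  s1 <- simulate_constant_current(3, 60, p1)$spikes
  s2 <- simulate_constant_current(3, 60, p2)$spikes
  n <- min(length(s1), length(s2))
  expect_gt(n, 3)
  expect_true(all(abs(s1[1:n] - s2[1:n]) <= 0.02 + 1e-12))
})

test_that("Euler trace converges first-order to the closed form", {
  for (ri0 in c(0.5, 1.5, 3)) {
    errs <- sapply(c(0.04, 0.02, 0.01), function(dt) {
      p <- lif_params(v_th = 1e6, dt = dt)  # threshold out of reach: pure charging
      sim <- simulate_constant_current(ri0, 50, p)
      max(abs(sim$trace$voltage_mV -
                membrane_closed_form(sim$trace$time_ms, ri0, p)))
    })
    ratio <- errs[-3] / errs[-1]
    expect_true(all(ratio > 2 * 0.8 & ratio < 2 * 1.2))
  }
})

test_that("spike count over a horizon follows the interval recurrence", {
  p <- lif_params()
  for (ri0 in c(1.2, 2, 5, 20)) {
    sim <- simulate_constant_current(ri0, 200, p)
    period <- first_spike_interval(ri0, p) + p$tau_ref
    predicted <- floor((200 - first_spike_interval(ri0, p)) / period) + 1
    expect_lte(abs(length(sim$spikes) - predicted), 1)
  }
})

test_that("sampled drive must match the horizon and be finite", {
  p <- lif_params()
  expect_error(simulate_constant_current(rep(1, 10), 100, p), "samples")
  expect_error(simulate_constant_current(c(rep(1, 9999), NA), 100, p), "finite")
})
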