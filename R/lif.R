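#' Leaky integrate-and-fire neuron parameters
#'
#' Constructs a validated parameter set for the leaky integrate-and-fire
#' (LIF) neuron model
#' \deqn{\tau \frac{dV_m}{dt} = -(V_m - V_{rest}) + R_m I(t),}
#' where \eqn{\tau = R_m C_m} is the membrane time constant. Defaults are the
#' experiment settings used throughout the package: resting and reset
#' potentials at 0 mV, a 1.0 mV firing threshold, a 10 ms time constant, a
#' 1 ms absolute refractory period and a 0.01 ms integration step.
#'
#' Because the drive is always specified as the product \eqn{R_m I_0} (a
#' voltage, in mV), the individual values of \eqn{C_m} and \eqn{R_m} never
#' enter the dynamics and need not be supplied.
#'
#' @param v_rest resting potential (mV).
#' @param v_th firing threshold (mV); must exceed `v_rest`.
#' @param v_reset post-spike reset potential (mV); must not exceed `v_th`.
#' @param tau membrane time constant \eqn{\tau} (ms), positive.
#' @param tau_ref absolute refractory period (ms), non-negative.
#' @param dt integration step (ms); must satisfy `dt <= tau / 10`.
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params()
#' membrane_closed_form(10 * log(2), ri0 = 2, p)  # 1 mV at t = tau*ln 2
#' @export
lif_params <- function(v_rest = 0, v_th = 1.0, v_reset = 0,
                       tau = 10, tau_ref = 1, dt = 0.01) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(dt), length(dt) == 1L, is.finite(dt))
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (dt > tau / 10) {
    stop("`dt` must be at most tau/10 for a stable explicit-Euler step",
         call. = FALSE)
  }
  if (!(v_th > v_rest)) stop("`v_th` must exceed `v_rest`", call. = FALSE)
  if (v_reset > v_th) stop("`v_reset` must not exceed `v_th`", call. = FALSE)
  if (tau_ref < 0) stop("`tau_ref` must be non-negative", call. = FALSE)
  structure(
    list(v_rest = v_rest, v_th = v_th, v_reset = v_reset,
         tau = tau, tau_ref = tau_ref, dt = dt),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF neuron parameters\n")
  cat(sprintf("  Vrest %g mV | Vth %g mV | Vreset %g mV\n",
              x$v_rest, x$v_th, x$v_reset))
  cat(sprintf("  tau %g ms | tau_ref %g ms | dt %g ms\n",
              x$tau, x$tau_ref, x$dt))
  invisible(x)
}

#' Closed-form membrane potential under constant drive
#'
#' For a LIF neuron starting at its resting potential and driven by a
#' constant current \eqn{I_0}, the membrane charges as
#' \deqn{V_m(t) = R_m I_0 (1 - e^{-t/\tau}) + V_{rest}.}
#' `t_elapsed` is time since the last reset (the previous spike, or
#' stimulus onset).
#'
#' @param t_elapsed time since last reset (ms), non-negative; vectorised.
#' @param ri0 drive expressed as the voltage \eqn{R_m I_0} (mV).
#' @param params a [lif_params()] object.
#' @return Membrane potential(s) in mV.
#' @export
membrane_closed_form <- function(t_elapsed, ri0, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"), is.numeric(t_elapsed))
  if (any(t_elapsed < 0)) {
    stop("`t_elapsed` must be non-negative", call. = FALSE)
  }
  ri0 * (1 - exp(-t_elapsed / params$tau)) + params$v_rest
}

#' Closed-form interspike interval under constant drive
#'
#' Inverts the charging curve at the firing threshold: the neuron reaches
#' \eqn{V_{th}} after
#' \deqn{\Delta T = \tau \,\ln\!\frac{R_m I_0}{R_m I_0 - (V_{th}-V_{rest})}}
#' whenever the asymptotic depolarisation \eqn{R_m I_0} exceeds the distance
#' to threshold; otherwise the neuron never fires and `NA` is returned (a
#' value, not an error). The full period between spikes is
#' `first_spike_interval(...) + tau_ref`.
#'
#' @inheritParams membrane_closed_form
#' @return Interval \eqn{\Delta T} in ms, or `NA_real_` when the threshold is
#'   never reached (including `ri0` exactly at threshold, the asymptotic
#'   case).
#' @export
first_spike_interval <- function(ri0, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"))
  gap <- params$v_th - params$v_rest
  ifelse(ri0 <= gap, NA_real_, params$tau * log(ri0 / (ri0 - gap)))
}

#' Simulate a LIF neuron under constant current
#'
#' Explicit-Euler integration of the membrane equation at step `dt`:
#' \eqn{V \leftarrow V + \frac{dt}{\tau}\,(-(V - V_{rest}) + R_m I_0)}. A
#' spike is recorded at the first sampled step where \eqn{V \ge V_{th}}
#' (no sub-step interpolation); the membrane is then clamped at
#' \eqn{V_{reset}} for `tau_ref` milliseconds, during which the drive is
#' ignored. The recorded trace stores the post-reset value at spike steps so
#' no sample exceeds threshold.
#'
#' @param ri0 drive as the voltage \eqn{R_m I_0} (mV); either a single
#'   constant or a vector sampled at `dt` covering the horizon.
#' @param horizon simulation length (ms), positive.
#' @param params a [lif_params()] object.
#' @return A list of class `lif_sim` with elements `trace` (data.frame
#'   `time_ms`, `voltage_mV`), `spikes` (numeric vector of spike times, ms)
#'   and `horizon`.
#' @export
simulate_constant_current <- function(ri0, horizon, params = lif_params()) {
  if (!inherits(params, "lif_params")) {
    stop("`params` must be created with lif_params()", call. = FALSE)
  }
  stopifnot(is.numeric(horizon), length(horizon) == 1L)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  dt <- params$dt
  n <- floor(horizon / dt)
  times <- seq_len(n) * dt
  drive <- if (length(ri0) == 1L) rep(ri0, n) else ri0
  if (length(drive) != n) {
    stop(sprintf("sampled drive must have %d samples to cover the horizon", n),
         call. = FALSE)
  }
  if (any(!is.finite(drive))) stop("drive must be finite", call. = FALSE)

  v <- params$v_rest
  volt <- numeric(n)
  spikes <- numeric(0)
  ref_steps <- ceiling(params$tau_ref / dt)
  ref_left <- 0L
  for (i in seq_len(n)) {
    if (ref_left > 0L) {
      v <- params$v_reset
      ref_left <- ref_left - 1L
    } else {
      v <- v + dt / params$tau * (-(v - params$v_rest) + drive[i])
      if (v >= params$v_th) {
        spikes <- c(spikes, times[i])
        v <- params$v_reset
        ref_left <- ref_steps
      }
    }
    volt[i] <- v
  }
  structure(
    list(trace = data.frame(time_ms = times, voltage_mV = volt),
         spikes = spikes, horizon = horizon, params = params),
    class = "lif_sim"
  )
}

#' @export
print.lif_sim <- function(x, ...) {
  cat(sprintf("LIF simulation: %.4g ms horizon, %d spikes\n",
              x$horizon, length(x$spikes)))
  if (length(x$spikes) > 0) {
    cat("  first spikes (ms):",
        paste(signif(utils::head(x$spikes, 5), 6), collapse = ", "), "\n")
  }
  invisible(x)
}
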