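#' Five-parameter gating rate model
#'
#' Every voltage-dependent gate in the model uses opening/closing rates
#' `alpha(V) = x1 * exp(V / x2)` and `beta(V) = x3 * exp(V / x4)`, with
#' `tau = 1 / (alpha + beta) + x5` and steady state `n_inf = alpha /
#' (alpha + beta)`. `x5` is an additive floor on the time constant.
#'
#' @param V membrane potential (mV). Vectorized.
#' @param p rate parameters: list or named vector with `x1` (1/ms), `x2`
#'   (mV), `x3` (1/ms), `x4` (mV), `x5` (ms).
#' @return List with vectors `alpha`, `beta` (1/ms), `tau` (ms), `n_inf`.
#' @examples
#' rates(0, rate_params(0.02, 22, 0.02, -22, 1))$n_inf # 0.5 by symmetry
#' @export
rates <- function(V, p) {
  p <- as.list(p)
  if (p$x1 <= 0 || p$x3 <= 0) stop("rates: x1 and x3 must be positive")
  if (p$x2 == 0 || p$x4 == 0) stop("rates: x2 and x4 must be non-zero")
  if (p$x5 < 0) stop("rates: x5 must be non-negative")
  a <- p$x1 * exp(V / p$x2)
  b <- p$x3 * exp(V / p$x4)
  list(alpha = a, beta = b, tau = 1 / (a + b) + p$x5, n_inf = a / (a + b))
}

#' Construct gating rate parameters
#'
#' @param x1,x3 rate scales (1/ms, > 0).
#' @param x2,x4 voltage sensitivities (mV, non-zero).
#' @param x5 additive time-constant floor (ms, >= 0).
#' @return Named list of class `vsm_rate_params`.
#' @export
rate_params <- function(x1, x2, x3, x4, x5 = 0) {
  p <- list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5)
  structure(p, class = "vsm_rate_params")
}

#' Rate parameters realizing a Boltzmann steady state
#'
#' Builds [rate_params()] whose steady state is exactly the Boltzmann
#' `1 / (1 + exp(-(V - v_half)/k))` (increasing for `k > 0`, decreasing for
#' `k < 0`), with a bell-shaped time constant peaking at `tau_max` near
#' `v_half` plus the floor `tau_floor`.
#'
#' Using `x2 = 2k`, `x4 = -2k` gives `n_inf = 1/(1 + (x3/x1) exp(-V/k))`, so
#' `x3/x1 = exp(v_half/k)` places the half-activation at `v_half`.
#'
#' @param v_half half-activation voltage (mV).
#' @param k slope factor (mV); negative for inactivation-type gates.
#' @param tau_max peak of the voltage-dependent part of tau (ms).
#' @param tau_floor additive floor x5 (ms).
#' @return A `vsm_rate_params` object.
#' @export
boltzmann_rate_params <- function(v_half, k, tau_max, tau_floor = 0) {
  stopifnot(k != 0, tau_max > tau_floor)
  # tau(v_half) - x5 = 1/(2 * x1 * exp(v_half/(2k)))
  x1 <- exp(-v_half / (2 * k)) / (2 * (tau_max - tau_floor))
  rate_params(
    x1 = x1, x2 = 2 * k,
    x3 = x1 * exp(v_half / k), x4 = -2 * k,
    x5 = tau_floor
  )
}

#' Steady-state value and time constant for one gate
#'
#' @param V membrane potential (mV).
#' @param p `vsm_rate_params`.
#' @return List with `n_inf` and `tau`.
#' @export
gate_ss <- function(V, p) {
  r <- rates(V, p)
  list(n_inf = r$n_inf, tau = r$tau)
}
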