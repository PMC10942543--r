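#' Voltage-clamp step protocol
#'
#' @param holding holding potential (mV).
#' @param steps vector of step potentials (mV).
#' @param step_ms step duration (ms).
#' @param pre_ms time at holding before each step (ms).
#' @return List of class `vsm_clamp_protocol`.
#' @export
clamp_protocol <- function(holding = -80, steps = seq(-60, 60, 10),
                           step_ms = 500, pre_ms = 1000) {
  stopifnot(step_ms > 0, pre_ms >= 0)
  structure(list(holding = holding, steps = steps, step_ms = step_ms,
                 pre_ms = pre_ms), class = "vsm_clamp_protocol")
}

#' Drug block description
#'
#' @param target current name as used by [scale_parameter()] mapping:
#'   one of `"I_Ca"`, `"I_Kv21"`, `"I_Kv15"`, `"I_BK"`, `"I_NSC"`.
#' @param fraction blocked fraction in `[0, 1]`.
#' @param label free-text concentration label.
#' @return List of class `vsm_drug_block`.
#' @export
drug_block <- function(target = "I_Ca", fraction = 0.65,
                       label = "nifedipine 0.1 uM") {
  if (fraction < 0 || fraction > 1) {
    stop("drug_block: fraction must lie in [0, 1]")
  }
  structure(list(target = target, fraction = fraction, label = label),
            class = "vsm_drug_block")
}

.block_targets <- c(I_Ca = "P_Ca", I_Kv21 = "G_Kv21", I_Kv15 = "G_Kv15",
                    I_BK = "P_BKCa", I_NSC = "G_NSC")

#' Apply a drug block to a parameter set
#'
#' Scales the target current's permeability/conductance by
#' `1 - fraction`. Blocks compose multiplicatively: applying fractions `f`
#' then `g` equals one application of `1 - (1-f)(1-g)`.
#'
#' @param p a `vsm_params`.
#' @param block a `vsm_drug_block` (default: 65% L-type block, the
#'   midpoint of the reported 60-70% reduction at 0.1 uM nifedipine).
#' @return Modified `vsm_params`.
#' @export
apply_drug <- function(p, block = drug_block()) {
  if (!block$target %in% names(.block_targets)) {
    stop("apply_drug: unknown current: ", block$target)
  }
  scale_parameter(p, .block_targets[[block$target]], 1 - block$fraction)
}

#' Voltage-clamp I-V family for one current
#'
#' Runs the clamp protocol step by step and extracts, per step, the peak
#' current, the steady (end-of-step) current, and single-exponential time
#' constants of the activating and (for inactivating currents) decaying
#' phases.
#'
#' @param p a `vsm_params`.
#' @param protocol a `vsm_clamp_protocol`.
#' @param current one of the recorded current names (e.g. `"I_Kv21"`).
#' @param dt integration step (ms).
#' @return Data frame with columns `V_step`, `peak`, `steady`,
#'   `tau_act_ms`, `tau_inact_ms` (NA where a fit fails or does not apply).
#' @export
iv_family <- function(p, protocol = clamp_protocol(), current = "I_Kv21",
                      dt = 0.05) {
  if (!current %in% .current_names) {
    stop("iv_family: unknown current: ", current)
  }
  rows <- lapply(protocol$steps, function(vs) {
    vcmd <- function(t) ifelse(t < protocol$pre_ms, protocol$holding, vs)
    tr <- simulate(p, protocol$pre_ms + protocol$step_ms,
                   noise = noise_config(0, 0, 1, dt),
                   mode = "voltage_clamp", V_cmd = vcmd,
                   discard_ms = 0, sample_every_ms = dt)
    sel <- tr$time >= protocol$pre_ms
    t_step <- tr$time[sel] - protocol$pre_ms
    i_step <- tr$currents[sel, current]
    pk_i <- which.max(abs(i_step))
    peak <- i_step[pk_i]
    steady <- i_step[length(i_step)]
    tau_act <- .fit_single_exp(t_step[seq_len(pk_i)], i_step[seq_len(pk_i)])
    tau_inact <- if (pk_i < length(i_step) - 10 &&
                     abs(peak - steady) > 0.05 * abs(peak)) {
      .fit_single_exp(t_step[pk_i:length(i_step)] - t_step[pk_i],
                      i_step[pk_i:length(i_step)])
    } else {
      NA_real_
    }
    data.frame(V_step = vs, peak = peak, steady = steady,
               tau_act_ms = tau_act, tau_inact_ms = tau_inact)
  })
  do.call(rbind, rows)
}

# single-exponential fit y = y_inf + (y0 - y_inf) exp(-t/tau); returns tau
# (ms) or NA on failure
.fit_single_exp <- function(t, y) {
  if (length(t) < 8 || diff(range(y)) == 0) return(NA_real_)
  y_inf0 <- y[length(y)]
  y00 <- y[1]
  # start tau at the 63%-of-range crossing time
  frac <- abs(y - y00) / max(abs(y_inf0 - y00), 1e-12)
  i63 <- which(frac >= 0.632)[1]
  tau0 <- if (is.na(i63)) max(t[length(t)] / 5, 1e-3) else max(t[i63], 1e-3)
  fit <- tryCatch(
    suppressWarnings(
      nls(y ~ yinf + (y0 - yinf) * exp(-t / tau),
          start = list(yinf = y_inf0, y0 = y00, tau = tau0),
          control = nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL
  )
  tau <- if (!is.null(fit)) coef(fit)[["tau"]] else NA_real_
  if (is.finite(tau) && tau > 0) return(tau)
  # log-linear fallback with the end value as the asymptote
  resid <- abs(y - y_inf0)
  ok <- resid > 1e-9 * max(resid)
  if (sum(ok) < 4) return(NA_real_)
  sl <- stats::lm(log(resid[ok]) ~ t[ok])$coefficients[[2]]
  if (sl < 0) -1 / sl else NA_real_
}

#' Kv1.5/Kv2.1 contribution split at a clamped potential
#'
#' Deterministic steady-state decomposition of the total voltage-gated K+
#' current: `100 * I_Kv15 / (I_Kv15 + I_Kv21)` and the Kv2.1 complement.
#'
#' @param p a `vsm_params`.
#' @param V_hold clamped membrane potential (mV).
#' @return Named vector `c(pct_Kv15, pct_Kv21)`; sums to exactly 100.
#' @export
kv_contributions <- function(p, V_hold = -40) {
  cur <- steady_currents(p, V_hold)
  tot <- cur$I_Kv15 + cur$I_Kv21
  if (abs(tot) < 1e-12) {
    stop("kv_contributions: total Kv current is zero at V = ", V_hold)
  }
  c(pct_Kv15 = 100 * cur$I_Kv15 / tot, pct_Kv21 = 100 * cur$I_Kv21 / tot)
}

#' Open-channel count from a macroscopic current
#'
#' Divides the current magnitude by the single-channel current and rounds
#' to the nearest integer (ties round half away from zero).
#'
#' @param current macroscopic current (pA).
#' @param single_channel_current unitary current (pA, > 0); 0.7 pA is the
#'   Kv2.1 unitary current near -40/-30 mV.
#' @return List with `ratio` (raw quotient) and `count` (integer).
#' @export
channel_count <- function(current, single_channel_current = 0.7) {
  if (single_channel_current <= 0) {
    stop("channel_count: single-channel current must be positive")
  }
  ratio <- abs(current) / single_channel_current
  count <- floor(ratio + 0.5) # half away from zero for non-negative ratio
  list(ratio = ratio, count = as.integer(count))
}

#' Transient-hyperpolarization frequency of a voltage trace
#'
#' Detects downward crossings of (running-median baseline - threshold)
#' with a refractory period, and reports events per second.
#'
#' @param trace a `vsm_trace` from [simulate()], or a list with `time`
#'   (ms) and a `V` vector.
#' @param threshold_mV drop below baseline that counts as an event.
#' @param refractory_ms minimum spacing between events.
#' @param baseline_window_ms window of the running median (ms).
#' @return Frequency in Hz.
#' @export
th_frequency <- function(trace, threshold_mV = 5, refractory_ms = 100,
                         baseline_window_ms = 2000) {
  V <- if (!is.null(trace$state)) trace$state[, "V"] else trace$V
  t <- trace$time
  if (length(t) < 2) stop("th_frequency: trace too short")
  dur_s <- (t[length(t)] - t[1]) / 1000
  if (dur_s < 10) stop("th_frequency: need at least 10 s of signal")
  dt <- t[2] - t[1]
  k <- max(3, round(baseline_window_ms / dt))
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, length(V) - (1 - length(V) %% 2))
  base <- stats::runmed(V, k)
  below <- V < (base - threshold_mV)
  onsets <- which(diff(c(FALSE, below)) == 1)
  if (length(onsets) > 1) {
    keep <- c(TRUE, diff(t[onsets]) > refractory_ms)
    onsets <- onsets[keep]
  }
  length(onsets) / dur_s
}

#' Percent change between two scalars
#'
#' `100 * (before - after) / before`: positive for a reduction.
#'
#' @param before,after scalar values; `before` must be non-zero.
#' @return Percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("percent_change: zero baseline")
  100 * (before - after) / before
}
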