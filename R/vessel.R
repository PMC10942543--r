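#' Cable parameters for the 1D vessel
#'
#' @param N_cells number of coupled myocytes.
#' @param a fiber radius (um).
#' @param dx segment length (cm); default 0.01 cm = 100 um (one cell).
#' @param R_myo myoplasmic resistivity (Ohm cm).
#' @param R_g gap-junction resistance (Ohm cm^2); `Inf` uncouples the cable.
#' @param I_stim stimulus current density (pA/pF).
#' @return List of class `vsm_cable`.
#' @export
cable_params <- function(N_cells = 400, a = 5, dx = 0.01, R_myo = 150,
                         R_g = 71.4, I_stim = 0) {
  stopifnot(N_cells >= 1, a > 0, dx > 0, R_myo > 0, R_g > 0)
  structure(list(N_cells = as.integer(N_cells), a = a, dx = dx,
                 R_myo = R_myo, R_g = R_g, I_stim = I_stim),
            class = "vsm_cable")
}

# coupling rate in 1/ms: the finite-difference cable coefficient
# a / (4 (R_myo + R_g/dx)) / dx^2 divided by the specific membrane
# capacitance (1 uF/cm^2), converted from 1/s to 1/ms
.couple_rate <- function(cable) {
  if (is.infinite(cable$R_g)) return(0)
  a_cm <- cable$a * 1e-4
  r_eff <- cable$R_myo + cable$R_g / cable$dx # Ohm cm
  a_cm / (4 * r_eff * cable$dx^2 * 1e-6) / 1000
}

#' Gap-junction coupling term
#'
#' Per-cell coupling current density (pA/pF, equivalently mV/ms) from the
#' finite-difference cable equation with sealed (no-flux) ends:
#' `rate * (V[i-1] - 2 V[i] + V[i+1])` with mirrored boundary values.
#'
#' @param V vector of per-cell membrane potentials (mV).
#' @param cable a `vsm_cable`.
#' @return Vector of coupling current densities (pA/pF); sums to zero.
#' @export
coupling_term <- function(V, cable) {
  n <- length(V)
  if (n == 0) stop("coupling_term: empty voltage vector")
  vm <- c(V[1], V[-n])
  vp <- c(V[-1], V[n])
  .couple_rate(cable) * (vm - 2 * V + vp)
}

#' Simulate a 1D vessel of coupled myocytes
#'
#' Integrates `N_cells` copies of the single-cell model coupled through the
#' gap-junction cable term, each cell carrying an independent noise
#' substream derived from the master seed. Supports the uncoupled mode
#' (`R_g = Inf`).
#'
#' @param p a `vsm_params` object (homogeneous across the cable).
#' @param cable a `vsm_cable`.
#' @param duration_ms simulated time after the discard window (ms).
#' @param noise a `vsm_noise`; vessel runs are normally stochastic
#'   (physiological averaging requires fluctuations), the deterministic
#'   mode is retained for testing.
#' @param discard_ms equilibration window (ms) dropped from summaries.
#' @param sample_every_ms output sampling interval (ms).
#' @param state optional matrix (N_cells x 13) of initial states.
#' @param stream0 base index of the per-cell noise substreams.
#' @return A `vsm_vessel_trace`: `time` (ms), matrices `V` and `Ca_i`
#'   (samples x cells), per-sample spatial means `mean_V`, `mean_Ca_i`, and
#'   scalar time-space summaries `summary` (mean V, mean Ca_i over the
#'   analysis window).
#' @export
simulate_vessel <- function(p, cable = cable_params(), duration_ms = 30000,
                            noise = noise_config(dt = 0.05),
                            discard_ms = 10000, sample_every_ms = 5,
                            state = NULL, stream0 = 0L) {
  if (is.null(state)) {
    st <- initial_state(p)
    state <- matrix(rep(st, each = cable$N_cells), nrow = cable$N_cells)
  }
  res <- cpp_simulate_vessel(
    state, .flatten_params(p), .couple_rate(cable),
    discard_ms + duration_ms, noise$dt, noise$sigma_V, noise$sigma_SR,
    as.integer(noise$seed), as.integer(stream0), sample_every_ms
  )
  keep <- res$time >= discard_ms
  V <- res$V[keep, , drop = FALSE]
  Ca <- res$Ca_i[keep, , drop = FALSE]
  structure(list(
    time = res$time[keep] - discard_ms,
    V = V, Ca_i = Ca,
    mean_V = rowMeans(V), mean_Ca_i = rowMeans(Ca),
    final_states = res$final_states,
    summary = c(mean_V = mean(V), mean_Ca_i = mean(Ca)),
    meta = list(sex = p$sex, N_cells = cable$N_cells, R_g = cable$R_g,
                seed = noise$seed, dt = noise$dt)
  ), class = "vsm_vessel_trace")
}

#' Pressure-to-baseline-voltage map
#'
#' Intravascular pressure is represented through the NSC conductance: for a
#' requested pressure the map prescribes the baseline membrane potential the
#' NSC conductance is tuned to ([tune_nsc_for_baseline()]). Piecewise-linear
#' per sex through calibrated anchors at 20, 80 and 120 mmHg (at 80 mmHg the
#' vessel baselines match the sharp-electrode targets of about -45 mV male
#' and -35 mV female).
#'
#' @param sex `"male"` or `"female"`.
#' @return Function mapping pressure (mmHg) to target baseline V (mV).
#' @export
pressure_map <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  anchors <- if (sex == "male") {
    cbind(p = c(20, 80, 120), V = c(-52, -45, -42.5))
  } else {
    cbind(p = c(20, 80, 120), V = c(-42, -35, -31))
  }
  function(pressure) {
    stats::approx(anchors[, "p"], anchors[, "V"], xout = pressure,
                  rule = 2)$y
  }
}

#' Parameters at a given intravascular pressure
#'
#' Applies [pressure_map()] and retunes the NSC conductance.
#'
#' @param p a `vsm_params`.
#' @param pressure_mmHg intravascular pressure (mmHg).
#' @return Modified `vsm_params`.
#' @export
params_at_pressure <- function(p, pressure_mmHg) {
  tune_nsc_for_baseline(p, pressure_map(p$sex)(pressure_mmHg))
}

#' Pressure sweep of the coupled vessel
#'
#' For each pressure, tunes the NSC conductance per the pressure map,
#' simulates the coupled vessel, and reports time-and-space-averaged
#' cytosolic Ca2+ and membrane potential (optionally with an L-type block
#' applied).
#'
#' @param p a `vsm_params`.
#' @param pressures vector of pressures (mmHg).
#' @param cable a `vsm_cable`.
#' @param noise a `vsm_noise`.
#' @param duration_ms,discard_ms simulation windows (ms).
#' @param block optional `vsm_drug_block` (see [drug_block()]) applied
#'   before simulating.
#' @return Data frame with columns `pressure_mmHg`, `mean_Ca_i_nM`,
#'   `mean_V_mV`.
#' @export
pressure_sweep <- function(p, pressures, cable = cable_params(N_cells = 50),
                           noise = noise_config(dt = 0.05),
                           duration_ms = 20000, discard_ms = 10000,
                           block = NULL) {
  rows <- lapply(pressures, function(pr) {
    pp <- params_at_pressure(p, pr)
    if (!is.null(block)) pp <- apply_drug(pp, block)
    tr <- simulate_vessel(pp, cable, duration_ms, noise, discard_ms)
    data.frame(pressure_mmHg = pr,
               mean_Ca_i_nM = tr$summary[["mean_Ca_i"]] * 1e6,
               mean_V_mV = tr$summary[["mean_V"]])
  })
  do.call(rbind, rows)
}
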