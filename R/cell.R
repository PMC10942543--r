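# State vector layout shared with the compiled integrator
.state_names <- c("V", "dL", "dF", "X_Kv21act", "X_Kv15act", "X_ab",
                  "ryr_state", "Ca_i", "Ca_SR", "Ca_Jun", "BUF_CAM",
                  "Na_in", "K_in")

#' Default initial state
#'
#' Membrane potential at the sex-specific resting value with all gates at
#' their steady state for that voltage, cytosolic Ca2+ at 150 nM, SR load at
#' 120 uM, and bulk ions at the shipped concentrations.
#'
#' @param p a `vsm_params` object.
#' @param V optional starting membrane potential (mV); defaults to the
#'   sex-specific resting value (-40 male, -30 female).
#' @return Named numeric state vector.
#' @export
initial_state <- function(p, V = NULL) {
  if (is.null(V)) V <- if (p$sex == "male") -40 else -30
  conc <- p$conc
  Kd <- p$buffer$k_BUFoff / p$buffer$k_BUFon
  st <- c(
    V = V,
    dL = rates(V, p$gates$dL)$n_inf,
    dF = rates(V, p$gates$dF)$n_inf,
    X_Kv21act = rates(V, p$gates$kv21)$n_inf,
    X_Kv15act = rates(V, p$gates$kv15)$n_inf,
    X_ab = bk_activation_ss(V, conc$Ca_Jun * 1e3, p$channels),
    ryr_state = 0,
    Ca_i = conc$Ca_i, Ca_SR = conc$Ca_SR, Ca_Jun = conc$Ca_Jun,
    BUF_CAM = p$buffer$BUF_T * conc$Ca_i / (conc$Ca_i + Kd),
    Na_in = conc$Na_in, K_in = conc$K_in
  )
  st[.state_names]
}

#' All transmembrane currents at a given state
#'
#' Evaluates the 11 transmembrane currents plus the NSC components and
#' reversal potentials from the instantaneous state.
#'
#' @param state named state vector (see [initial_state()]).
#' @param p a `vsm_params` object.
#' @return Named list of currents (pA) and reversal potentials (mV);
#'   `I_ion` is the Eq.-of-motion sum of the 11 currents.
#' @export
compute_currents <- function(state, p) {
  s <- as.list(state)
  const <- p$const
  ch <- p$channels
  conc <- list(
    Na_in = s$Na_in, Na_out = p$conc$Na_out,
    K_in = s$K_in, K_out = p$conc$K_out,
    Ca_i = s$Ca_i, Ca_out = p$conc$Ca_out
  )
  E_K <- nernst(const$z_K, conc$K_in, conc$K_out, const)
  E_Na <- nernst(const$z_Na, conc$Na_in, conc$Na_out, const)
  E_Ca <- nernst(const$z_Ca, conc$Ca_i, conc$Ca_out, const)
  nsc <- i_nsc(s$V, conc, ch, const)
  cur <- list(
    I_Ca = i_ca(s$V, s$dL, s$dF, conc, ch, const),
    I_Kv21 = i_kv(s$V, s$X_Kv21act, ch$G_Kv21, E_K),
    I_Kv15 = i_kv(s$V, s$X_Kv15act, ch$G_Kv15, E_K),
    I_BK = i_bk(s$V, s$X_ab, conc, ch, const),
    I_NaNSC = nsc$I_NaNSC, I_KNSC = nsc$I_KNSC, I_NSC = nsc$I_NSC,
    I_NaK = i_nak(s$V, conc, ch, const),
    I_NCX = i_ncx(s$V, conc, ch, const),
    I_PMCA = i_pmca(s$Ca_i, ch),
    I_Nab = i_leak(s$V, ch$G_Nab, E_Na),
    I_Kb = i_leak(s$V, ch$G_Kb, E_K),
    I_Cab = i_leak(s$V, ch$G_Cab, E_Ca),
    E_K = E_K, E_Na = E_Na, E_Ca = E_Ca, E_NSC = nsc$E_NSC
  )
  cur$I_ion <- cur$I_Kv15 + cur$I_Kv21 + cur$I_BK + cur$I_Kb + cur$I_Ca +
    cur$I_PMCA + cur$I_Cab + cur$I_NCX + cur$I_NSC + cur$I_NaK + cur$I_Nab
  cur
}

#' Time derivatives of the full single-cell system
#'
#' In current-clamp mode `dV/dt = -I_ion/C_m`; in voltage-clamp mode the
#' membrane potential is held at `V_cmd` (`dV/dt = 0`) and the clamp current
#' equals `I_ion`. Gates relax first-order toward their voltage (and, for
#' BK, junctional-Ca2+) dependent steady states; concentrations follow
#' [ca_rhs()] and [na_k_rhs()].
#'
#' @param state named state vector.
#' @param p a `vsm_params` object.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param V_cmd command potential (mV) for voltage-clamp mode.
#' @return List with `dstate` (named vector) and `currents`.
#' @export
derivatives <- function(state, p, mode = c("current_clamp", "voltage_clamp"),
                        V_cmd = NULL) {
  mode <- match.arg(mode)
  s <- as.list(state)
  if (mode == "voltage_clamp") {
    if (is.null(V_cmd)) stop("derivatives: voltage clamp requires V_cmd")
    s$V <- V_cmd
    state[["V"]] <- V_cmd
  }
  cur <- compute_currents(state, p)
  gdL <- rates(s$V, p$gates$dL)
  gdF <- rates(s$V, p$gates$dF)
  g21 <- rates(s$V, p$gates$kv21)
  g15 <- rates(s$V, p$gates$kv15)
  xab_inf <- bk_activation_ss(s$V, s$Ca_Jun * 1e3, p$channels)
  xab_tau <- bk_tau(s$V, p$channels)
  r_inf <- ryr_inf(s$Ca_SR, s$Ca_Jun, p$sr)
  ca <- ca_rhs(s, cur, p)
  nak <- na_k_rhs(cur, p)
  dV <- if (mode == "current_clamp") -cur$I_ion / p$volumes$C_m else 0
  dstate <- c(
    V = dV,
    dL = (gdL$n_inf - s$dL) / gdL$tau,
    dF = (gdF$n_inf - s$dF) / gdF$tau,
    X_Kv21act = (g21$n_inf - s$X_Kv21act) / g21$tau,
    X_Kv15act = (g15$n_inf - s$X_Kv15act) / g15$tau,
    X_ab = (xab_inf - s$X_ab) / xab_tau,
    ryr_state = (r_inf - s$ryr_state) / p$sr$ryr_tau,
    Ca_i = ca$dCa_i, Ca_SR = ca$dCa_SR, Ca_Jun = ca$dCa_Jun,
    BUF_CAM = ca$dBUF_CAM,
    Na_in = if (p$clamp_ions) 0 else nak$dNa_in,
    K_in = if (p$clamp_ions) 0 else nak$dK_in
  )
  list(dstate = dstate[.state_names], currents = cur)
}

#' Noise configuration for stochastic simulations
#'
#' @param sigma_V amplitude of the Gaussian white-noise current expressed as
#'   a voltage diffusion coefficient (mV/sqrt(ms)).
#' @param sigma_SR diffusion coefficient applied to the SR Ca2+ update
#'   (mM/sqrt(ms)).
#' @param seed integer seed for the counter-based generator.
#' @param dt time step (ms).
#' @return List of class `vsm_noise`.
#' @export
noise_config <- function(sigma_V = 0.35, sigma_SR = 4e-6, seed = 1,
                         dt = 0.01) {
  stopifnot(sigma_V >= 0, sigma_SR >= 0, dt > 0)
  structure(list(sigma_V = sigma_V, sigma_SR = sigma_SR,
                 seed = as.integer(seed), dt = dt), class = "vsm_noise")
}

# Flatten params to the named numeric vector consumed by the compiled
# integrator. Order must match params_from_vector() in src/.
.flatten_params <- function(p) {
  ch <- p$channels
  g <- function(rp) unlist(rp[c("x1", "x2", "x3", "x4", "x5")])
  c(
    F = p$const$F, R = p$const$R, T = p$const$T,
    Na_out = p$conc$Na_out, K_out = p$conc$K_out, Ca_out = p$conc$Ca_out,
    Vol_cyt = p$volumes$Vol_cyt, Vol_SR = p$volumes$Vol_SR,
    Vol_Jun = p$volumes$Vol_Jun, C_m = p$volumes$C_m,
    P_Ca = ch$P_Ca, G_Kv21 = ch$G_Kv21, G_Kv15 = ch$G_Kv15,
    P_BKCa = ch$P_BKCa, N_BK = ch$N_BK,
    G_NaNSC = ch$G_NaNSC, G_KNSC = ch$G_KNSC,
    G_Nab = ch$G_Nab, G_Kb = ch$G_Kb, G_Cab = ch$G_Cab,
    I_NaKmax = ch$I_NaKmax, Km_NaK_K = ch$Km_NaK_K, Km_NaK_Na = ch$Km_NaK_Na,
    Q10 = ch$Q10,
    P_NCX = ch$P_NCX, gamma_x = ch$gamma_x, k_sat_NCX = ch$k_sat_NCX,
    I_PMCAbar = ch$I_PMCAbar, Km_PMCA = ch$Km_PMCA,
    bk_vh0 = ch$bk_vh0, bk_slope_ca = ch$bk_slope_ca, bk_k = ch$bk_k,
    bk_tau_scale = ch$bk_tau_scale, bk_tau_floor = ch$bk_tau_floor,
    dL = g(p$gates$dL), dF = g(p$gates$dF),
    kv21 = g(p$gates$kv21), kv15 = g(p$gates$kv15),
    serca_vmax = p$sr$serca_vmax, serca_km = p$sr$serca_km,
    ryr_nu_rel = p$sr$ryr_nu_rel, ryr_nu_leak = p$sr$ryr_nu_leak,
    ryr_thr = p$sr$ryr_thr, ryr_k = p$sr$ryr_k, ryr_kjun = p$sr$ryr_kjun,
    ryr_hill = p$sr$ryr_hill,
    ryr_tau = p$sr$ryr_tau, k_JunCyt = p$sr$k_JunCyt,
    k_BUFon = p$buffer$k_BUFon, k_BUFoff = p$buffer$k_BUFoff,
    BUF_T = p$buffer$BUF_T,
    clamp_ions = as.numeric(p$clamp_ions)
  )
}

#' Single Euler-Maruyama step (reference implementation)
#'
#' Forward-Euler deterministic update plus `sigma * randN * sqrt(dt)` noise
#' increments on the membrane potential and the SR Ca2+ concentration. With
#' both sigmas zero this is plain forward Euler. Gates are clamped to
#' `[0, 1]` after the update.
#'
#' @param state named state vector.
#' @param p a `vsm_params` object.
#' @param noise a `vsm_noise` configuration.
#' @param randn two standard-normal draws (for V and Ca_SR); supplied by the
#'   caller so that noise streams stay reproducible.
#' @param mode,V_cmd clamp mode, as in [derivatives()].
#' @return Updated named state vector.
#' @export
step_euler_maruyama <- function(state, p, noise, randn = c(0, 0),
                                mode = "current_clamp", V_cmd = NULL) {
  d <- derivatives(state, p, mode, V_cmd)$dstate
  ns <- state + d * noise$dt
  if (mode == "current_clamp") {
    ns[["V"]] <- ns[["V"]] + noise$sigma_V * randn[1] * sqrt(noise$dt)
  } else {
    ns[["V"]] <- V_cmd
  }
  ns[["Ca_SR"]] <- ns[["Ca_SR"]] + noise$sigma_SR * randn[2] * sqrt(noise$dt)
  for (g in c("dL", "dF", "X_Kv21act", "X_Kv15act", "X_ab", "ryr_state")) {
    ns[[g]] <- min(1, max(0, ns[[g]]))
  }
  if (!all(is.finite(ns))) {
    stop("step_euler_maruyama: non-finite state (integration failure)")
  }
  ns
}

#' Simulate a single myocyte
#'
#' Integrates the full single-cell system with the compiled Euler-Maruyama
#' stepper and returns a sampled trace. Events allow mid-run scaling of a
#' named parameter (drug application).
#'
#' @param p a `vsm_params` object.
#' @param duration_ms simulated time (ms) after the discard window.
#' @param noise a `vsm_noise` configuration (use `sigma_V = 0, sigma_SR = 0`
#'   for deterministic runs).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param V_cmd command potential (mV) for voltage clamp; may be a function
#'   of time (ms) for step protocols, evaluated on the integration grid.
#' @param state optional initial state; defaults to [initial_state()].
#' @param discard_ms equilibration window discarded from the output (ms).
#' @param sample_every_ms output sampling interval (ms).
#' @param events optional list of `list(t_ms =, parameter =, scale =)`
#'   applied in order during the run (times relative to the start of the
#'   run, including the discard window).
#' @param stream0 base index of the noise substream (vessel cell `i` uses
#'   substream `stream0 + i`, so a single-cell run with `stream0 = i`
#'   reproduces that cell's noise realization).
#' @return A `vsm_trace`: list with `time` (ms, zero at the end of the
#'   discard window), `state` (matrix), `currents` (matrix), and metadata.
#' @export
simulate <- function(p, duration_ms, noise = noise_config(),
                     mode = c("current_clamp", "voltage_clamp"),
                     V_cmd = NULL, state = NULL, discard_ms = 0,
                     sample_every_ms = 1, events = NULL, stream0 = 0L) {
  mode <- match.arg(mode)
  stopifnot(duration_ms > 0)
  if (is.null(state)) state <- initial_state(p)
  total <- discard_ms + duration_ms
  vcmd_vec <- NULL
  if (mode == "voltage_clamp") {
    if (is.null(V_cmd)) stop("simulate: voltage clamp requires V_cmd")
    n_steps <- ceiling(total / noise$dt)
    vcmd_vec <- if (is.function(V_cmd)) {
      V_cmd((seq_len(n_steps) - 1) * noise$dt)
    } else {
      rep(V_cmd, n_steps)
    }
    state[["V"]] <- vcmd_vec[1]
  }
  segs <- .event_segments(p, events, total)
  out_time <- c()
  out_state <- NULL
  out_cur <- NULL
  t0 <- 0
  cur_state <- state
  stream <- as.integer(stream0)
  for (seg in segs) {
    pv <- .flatten_params(seg$p)
    seg_len <- seg$t_end - t0
    if (seg_len <= 0) {
      t0 <- seg$t_end
      next
    }
    res <- cpp_simulate_cell(
      cur_state, pv, seg_len, noise$dt,
      noise$sigma_V, noise$sigma_SR,
      as.integer(noise$seed), stream,
      mode == "voltage_clamp",
      if (is.null(vcmd_vec)) numeric(0) else vcmd_vec,
      as.integer(round(t0 / noise$dt)),
      sample_every_ms
    )
    cur_state <- stats::setNames(res$final_state, .state_names)
    keep_t <- res$time + t0
    out_time <- c(out_time, keep_t)
    out_state <- rbind(out_state, res$state)
    out_cur <- rbind(out_cur, res$currents)
    t0 <- seg$t_end
    stream <- stream + 100000L
  }
  keep <- out_time >= discard_ms
  colnames(out_state) <- .state_names
  colnames(out_cur) <- .current_names
  structure(list(
    time = out_time[keep] - discard_ms,
    state = out_state[keep, , drop = FALSE],
    currents = out_cur[keep, , drop = FALSE],
    final_state = cur_state,
    meta = list(sex = p$sex, seed = noise$seed, dt = noise$dt, mode = mode,
                discard_ms = discard_ms,
                params_hash = .params_hash(p))
  ), class = "vsm_trace")
}

.current_names <- c("I_Ca", "I_Kv21", "I_Kv15", "I_BK", "I_NSC", "I_NaK",
                    "I_NCX", "I_PMCA", "I_Nab", "I_Kb", "I_Cab", "I_ion")

.params_hash <- function(p) {
  v <- .flatten_params(p)
  # order-stable, text-friendly checksum without extra dependencies
  s <- paste(names(v), formatC(v, digits = 12, format = "g"),
             collapse = ";")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

# Split a run into constant-parameter segments at event times
.event_segments <- function(p, events, total) {
  if (is.null(events) || !length(events)) {
    return(list(list(p = p, t_end = total)))
  }
  ord <- order(vapply(events, function(e) e$t_ms, numeric(1)))
  events <- events[ord]
  segs <- list()
  cur <- p
  t_prev <- 0
  for (e in events) {
    if (e$t_ms > t_prev) {
      segs[[length(segs) + 1]] <- list(p = cur, t_end = e$t_ms)
    }
    cur <- scale_parameter(cur, e$parameter, e$scale)
    t_prev <- e$t_ms
  }
  segs[[length(segs) + 1]] <- list(p = cur, t_end = total)
  segs
}

#' Write a trace to tidy CSV
#'
#' One row per sample: time, state variables, per-current values; metadata
#' (sex, seed, dt, parameter hash) in `#`-prefixed header lines.
#'
#' @param trace a `vsm_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- trace$meta
  writeLines(sprintf("# vsmsim trace: sex=%s seed=%d dt=%g mode=%s hash=%s",
                     meta$sex, meta$seed, meta$dt, meta$mode,
                     format(meta$params_hash)), con)
  df <- data.frame(time_ms = trace$time, trace$state, trace$currents,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
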