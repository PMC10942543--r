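# Deterministic steady states of the clamped system.
#
# At a clamped membrane potential the gates sit at their steady states and
# cytosolic Ca2+ is set by the sarcolemmal Ca2+ current balance alone (the
# SR and junctional fluxes cancel pairwise in any stationary or
# cycle-averaged regime). Two reference states are distinguished:
#
# * fixed_state(): the true mathematical fixed point of the clamped system
#   (all derivatives zero). In the oscillatory spark regime this point is
#   unstable and its SR load sits above the physiological band -- it is the
#   point the spark-STOC limit cycle revolves around.
# * baseline_state(): the inter-spark operating point (RyR release at its
#   quiescent leak level, SR at the release threshold). This is the state
#   that matches the observable baseline between transient
#   hyperpolarizations and is used for NSC tuning and steady-state current
#   readouts. The membrane currents that do not sense junctional Ca2+ are
#   identical in the two states.

# cytosolic Ca2+ at the sarcolemmal balance point for clamped V
.ca_balance_root <- function(p, V) {
  ch <- p$channels
  const <- p$const
  dL <- rates(V, p$gates$dL)$n_inf
  dF <- rates(V, p$gates$dF)$n_inf
  f <- function(Ca) {
    conc <- p$conc
    conc$Ca_i <- Ca
    E_Ca <- nernst(const$z_Ca, Ca, conc$Ca_out, const)
    ica <- i_ca(V, dL, dF, conc, ch, const)
    icab <- i_leak(V, ch$G_Cab, E_Ca)
    ipm <- i_pmca(Ca, ch)
    incx <- i_ncx(V, conc, ch, const)
    ica + icab + ipm - 2 * incx
  }
  uniroot(f, lower = 1e-7, upper = 0.02, tol = 1e-14)$root
}

.assemble_state <- function(p, V, Ca, Ca_SR, Ca_Jun, r) {
  Kd <- p$buffer$k_BUFoff / p$buffer$k_BUFon
  st <- c(
    V = V,
    dL = rates(V, p$gates$dL)$n_inf,
    dF = rates(V, p$gates$dF)$n_inf,
    X_Kv21act = rates(V, p$gates$kv21)$n_inf,
    X_Kv15act = rates(V, p$gates$kv15)$n_inf,
    X_ab = bk_activation_ss(V, Ca_Jun * 1e3, p$channels),
    ryr_state = r,
    Ca_i = Ca, Ca_SR = Ca_SR, Ca_Jun = Ca_Jun,
    BUF_CAM = p$buffer$BUF_T * Ca / (Ca + Kd),
    Na_in = p$conc$Na_in, K_in = p$conc$K_in
  )
  st[.state_names]
}

#' True fixed point of the clamped cell
#'
#' Computes the state at which every derivative of the clamped single-cell
#' system vanishes: gates at steady state, cytosolic Ca2+ at the
#' sarcolemmal balance point, junctional Ca2+ at the transfer balance, and
#' the SR load at which gated + leak RyR release exactly matches SERCA
#' uptake with the RyR gate at its own steady state. In the oscillatory
#' regime this point is unstable (the spark cycle revolves around it) and
#' its SR load lies above the physiological band.
#'
#' @param p a `vsm_params` object.
#' @param V clamped membrane potential (mV).
#' @return Named state vector (see [initial_state()]).
#' @export
fixed_state <- function(p, V) {
  Ca <- .ca_balance_root(p, V)
  s <- j_serca(Ca, NA, p$sr)
  Ca_Jun <- Ca + s / p$sr$k_JunCyt
  g <- function(Ca_SR) {
    r <- ryr_inf(Ca_SR, Ca_Jun, p$sr)
    j_ryr(Ca_SR, Ca_Jun, r, p$sr) - s
  }
  Ca_SR <- uniroot(g, lower = Ca_Jun + 1e-9, upper = 50, tol = 1e-15)$root
  r <- ryr_inf(Ca_SR, Ca_Jun, p$sr)
  .assemble_state(p, V, Ca, Ca_SR, Ca_Jun, r)
}

#' Inter-spark baseline state of the clamped cell
#'
#' The quiescent operating point between Ca2+ sparks: cytosolic Ca2+ at the
#' sarcolemmal balance point, SR at the release threshold, and the
#' junctional domain at the balance of leak release against
#' junction-to-cytosol transfer (solved self-consistently with the RyR
#' steady-state open fraction). This is the state whose currents match the
#' observable baseline between transient hyperpolarizations.
#'
#' @param p a `vsm_params` object.
#' @param V clamped membrane potential (mV).
#' @return Named state vector.
#' @export
baseline_state <- function(p, V) {
  Ca <- .ca_balance_root(p, V)
  # representative of the loading phase: just below the release threshold
  Ca_SR <- p$sr$ryr_thr - 3 * p$sr$ryr_k
  Ca_Jun <- Ca
  for (i in 1:200) {
    r <- ryr_inf(Ca_SR, Ca_Jun, p$sr)
    target <- Ca + j_ryr(Ca_SR, Ca_Jun, r, p$sr) / p$sr$k_JunCyt
    Ca_Jun_new <- Ca_Jun + 0.5 * (target - Ca_Jun)
    if (abs(Ca_Jun_new - Ca_Jun) < 1e-16) break
    Ca_Jun <- Ca_Jun_new
  }
  .assemble_state(p, V, Ca, Ca_SR, Ca_Jun, ryr_inf(Ca_SR, Ca_Jun, p$sr))
}

#' Steady-state currents at a clamped potential
#'
#' Currents at the inter-spark baseline state ([baseline_state()]); the Kv,
#' L-type, pump and exchanger currents are identical at the true fixed
#' point.
#'
#' @param p a `vsm_params` object.
#' @param V clamped membrane potential (mV).
#' @return Named list of steady currents (pA).
#' @export
steady_currents <- function(p, V) {
  compute_currents(baseline_state(p, V), p)
}

#' Rescale the NSC conductance so the resting potential equals a target
#'
#' Scales the Na+ and K+ components of the nonselective cation conductance
#' jointly (fixed ratio) so that the total membrane current vanishes at the
#' inter-spark baseline state for `V_target`: the deterministic baseline of
#' the free-running cell then sits at `V_target`. This is the model's proxy
#' for pressure-induced depolarization.
#'
#' @param p a `vsm_params` object.
#' @param V_target desired baseline membrane potential (mV).
#' @return Modified `vsm_params` with rescaled `G_NaNSC`, `G_KNSC`.
#' @export
tune_nsc_for_baseline <- function(p, V_target) {
  cur <- steady_currents(p, V_target)
  i_other <- cur$I_ion - cur$I_NSC
  g_tot <- p$channels$G_NaNSC + p$channels$G_KNSC
  drive <- V_target - cur$E_NSC
  g_needed <- -i_other / drive
  if (g_needed < 0) {
    stop("tune_nsc_for_baseline: target requires negative NSC conductance")
  }
  scale_parameter(p, "G_NSC", g_needed / g_tot)
}

#' Current-clamp baseline equilibrium of the cell
#'
#' Finds the membrane potential at which the total ionic current through
#' the inter-spark baseline state vanishes: the deterministic operating
#' point of the free-running cell between sparks.
#'
#' @param p a `vsm_params` object.
#' @param interval search interval for V (mV).
#' @return List with `V` (mV) and `state` (named vector).
#' @export
find_equilibrium <- function(p, interval = c(-80, -10)) {
  f <- function(V) steady_currents(p, V)$I_ion
  V <- uniroot(f, lower = interval[1], upper = interval[2], tol = 1e-10)$root
  list(V = V, state = baseline_state(p, V))
}
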