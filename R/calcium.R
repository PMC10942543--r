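#' SERCA uptake flux
#'
#' Saturating (Hill n = 1) SR Ca-ATPase uptake, cytosol-referenced (mM/ms of
#' cytosolic volume). Removes Ca2+ from the cytosol; the SR gains the same
#' flux scaled by `Vol_cyt/Vol_SR`.
#'
#' @param Ca_i cytosolic free Ca2+ (mM, >= 0).
#' @param Ca_SR SR Ca2+ (mM); unused by the pump itself, kept in the
#'   signature for flux-balance bookkeeping.
#' @param p SR flux parameters (`serca_vmax` mM/ms, `serca_km` mM).
#' @return Uptake flux (mM/ms, >= 0).
#' @export
j_serca <- function(Ca_i, Ca_SR, p) {
  if (any(Ca_i < 0)) stop("j_serca: Ca_i must be non-negative")
  p$serca_vmax * Ca_i / (Ca_i + p$serca_km)
}

#' RyR release flux into the junctional domain
#'
#' Release proportional to the SR-junction gradient with a constant leak
#' pathway and a gated pathway: `(nu_leak + nu_rel * r) * (Ca_SR - Ca_Jun)`,
#' cytosol-referenced (mM/ms). The gated open fraction `r` follows
#' [ryr_inf()].
#'
#' @param Ca_SR,Ca_Jun SR and junctional Ca2+ (mM).
#' @param ryr_state gated open fraction in `[0, 1]`.
#' @param p SR flux parameters (`ryr_nu_rel`, `ryr_nu_leak`, 1/ms).
#' @return Release flux (mM/ms).
#' @export
j_ryr <- function(Ca_SR, Ca_Jun, ryr_state, p) {
  if (any(ryr_state < 0 | ryr_state > 1)) {
    stop("j_ryr: ryr_state must lie in [0, 1]")
  }
  (p$ryr_nu_leak + p$ryr_nu_rel * ryr_state) * (Ca_SR - Ca_Jun)
}

#' Steady-state RyR open fraction
#'
#' The gated release is driven by SR load through a steep sigmoid (release
#' probability correlates with SR load) and by junctional Ca2+ through a
#' Hill term with exponent `ryr_hill` (Ca-induced Ca release). The product
#' yields a
#' fire-and-reload relaxation oscillator: SERCA loads the SR until the load
#' threshold is crossed, regenerative release then dumps Ca2+ into the
#' junction (a spark) until the SR falls back below threshold.
#'
#' @param Ca_SR SR Ca2+ (mM).
#' @param Ca_Jun junctional Ca2+ (mM).
#' @param p SR flux parameters (`ryr_thr` mM, `ryr_k` mM, `ryr_kjun` mM,
#'   `ryr_hill`).
#' @return Open fraction in `[0, 1]`.
#' @export
ryr_inf <- function(Ca_SR, Ca_Jun, p) {
  phi <- 1 / (1 + exp(-(Ca_SR - p$ryr_thr) / p$ryr_k))
  n <- p$ryr_hill
  psi <- Ca_Jun^n / (Ca_Jun^n + p$ryr_kjun^n)
  phi * psi
}

#' Junction-to-cytosol diffusion flux
#'
#' First-order transfer `k_JunCyt * (Ca_Jun - Ca_i)`, cytosol-referenced
#' (mM/ms). Positive flux moves Ca2+ from the junctional domain into the
#' cytosol; the junction loses the same flux scaled by `Vol_cyt/Vol_Jun`.
#'
#' @param Ca_Jun,Ca_i junctional and cytosolic Ca2+ (mM).
#' @param p SR flux parameters (`k_JunCyt`, 1/ms).
#' @return Transfer flux (mM/ms).
#' @export
j_jun_cyt <- function(Ca_Jun, Ca_i, p) {
  p$k_JunCyt * (Ca_Jun - Ca_i)
}

#' Calcium-compartment right-hand sides
#'
#' Concentration derivatives for the cytosol, SR, junctional domain and
#' calmodulin buffer. The sarcolemmal term converts the Ca-carrying membrane
#' currents to a cytosolic flux: `-(I_Ca + I_Ca,b + I_PMCA - 2*I_NCX) /
#' (z_Ca * F * Vol_cyt)` (outward-positive currents; positive NCX current is
#' reverse-mode Ca2+ entry carrying one Ca2+ per elementary charge).
#'
#' @param state list with `Ca_i`, `Ca_SR`, `Ca_Jun`, `BUF_CAM` (mM) and
#'   `ryr_state`.
#' @param currents list with `I_Ca`, `I_Cab`, `I_PMCA`, `I_NCX` (pA).
#' @param p full model parameters (volumes, buffer and SR flux parameters).
#' @return List with `dCa_i`, `dCa_SR`, `dCa_Jun`, `dBUF_CAM` (mM/ms).
#' @export
ca_rhs <- function(state, currents, p) {
  const <- p$const
  vols <- p$volumes
  jser <- j_serca(state$Ca_i, state$Ca_SR, p$sr)
  jryr <- j_ryr(state$Ca_SR, state$Ca_Jun, state$ryr_state, p$sr)
  jjc <- j_jun_cyt(state$Ca_Jun, state$Ca_i, p$sr)
  # pA / (C/mol * L) -> 1e-12 A / (C/mol * L) = 1e-12 mol/(L s) = 1e-12 M/s
  # = 1e-12 * 1e3 mM / 1e3 ms = 1e-12 mM/ms per (F * Vol) unit
  sarc <- -(currents$I_Ca + currents$I_Cab + currents$I_PMCA -
    2 * currents$I_NCX) / (const$z_Ca * const$F * vols$Vol_cyt) * 1e-12
  buf <- p$buffer$k_BUFon * state$Ca_i * (p$buffer$BUF_T - state$BUF_CAM) -
    p$buffer$k_BUFoff * state$BUF_CAM
  list(
    dCa_i = sarc - jser + jjc - buf,
    dCa_SR = (vols$Vol_cyt / vols$Vol_SR) * (jser - jryr),
    dCa_Jun = (vols$Vol_cyt / vols$Vol_Jun) * (jryr - jjc),
    dBUF_CAM = buf
  )
}

#' Bulk Na+/K+ right-hand sides
#'
#' `dK/dt = -(I_Kv2.1 + I_Kv1.5 + I_BK + I_K,b - 2*I_NaK + I_KNSC) /
#' (z_K * F * Vol_cyt)` and `dNa/dt = -(3*I_NCX + 3*I_NaK + I_Na,b +
#' I_NaNSC) / (z_Na * F * Vol_cyt)`. With bulk ion clamping enabled
#' (the default in shipped parameter sets) these derivatives are computed
#' but not applied by the integrator.
#'
#' @param currents list of per-current values (pA).
#' @param p full model parameters.
#' @return List with `dNa_in`, `dK_in` (mM/ms).
#' @export
na_k_rhs <- function(currents, p) {
  const <- p$const
  denom <- const$F * p$volumes$Vol_cyt
  dK <- -(currents$I_Kv21 + currents$I_Kv15 + currents$I_BK +
    currents$I_Kb - 2 * currents$I_NaK + currents$I_KNSC) /
    (const$z_K * denom) * 1e-12
  dNa <- -(3 * currents$I_NCX + 3 * currents$I_NaK + currents$I_Nab +
    currents$I_NaNSC) / (const$z_Na * denom) * 1e-12
  list(dNa_in = dNa, dK_in = dK)
}
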