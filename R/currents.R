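#' Nernst (equilibrium) potential
#'
#' @param z ion valence (non-zero integer).
#' @param c_in,c_out intracellular and extracellular concentrations (mM, > 0).
#' @param const physical constants, see [physical_constants()].
#' @return Reversal potential in mV.
#' @examples
#' const <- physical_constants()
#' conc <- default_concentrations()
#' nernst(1, conc$K_in, conc$K_out, const) # E_K, about -84 mV
#' @export
nernst <- function(z, c_in, c_out, const = physical_constants()) {
  if (any(c_in <= 0) || any(c_out <= 0)) {
    stop("nernst: concentrations must be positive")
  }
  if (any(z == 0)) stop("nernst: valence must be non-zero")
  rtf_mv(const) / z * log(c_out / c_in)
}

#' Goldman-Hodgkin-Katz (constant-field) current
#'
#' Computes `P * z * F * u * (c_in * exp(u) - c_out) / (exp(u) - 1)` with
#' `u = z*V*F/(R*T)` (dimensionless). At `V = 0` the removable singularity is
#' replaced by the analytic limit `P * z * F * (c_in - c_out)`; near zero a
#' series expansion is used for numerical continuity. Outward current is
#' positive. The permeability `P` is a calibrated scale absorbing membrane
#' area and unit conversions so that the result is in pA for concentrations
#' in mM and voltage in mV.
#'
#' @param V membrane potential (mV). Vectorized.
#' @param z ion valence.
#' @param P permeability scale (>= 0).
#' @param c_in,c_out concentrations (mM).
#' @param const physical constants.
#' @return Current in pA (outward positive).
#' @export
ghk_current <- function(V, z, P, c_in, c_out, const = physical_constants()) {
  if (any(P < 0)) stop("ghk_current: permeability must be non-negative")
  u <- z * V / rtf_mv(const)
  zF <- z * const$F
  small <- abs(u) < 1e-4
  out <- numeric(length(u))
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- zF * us * (c_in * exp(us) - c_out) / (exp(us) - 1)
  }
  if (any(small)) {
    us <- u[small]
    # u*(ci e^u - co)/(e^u - 1) = (ci - co) + u*(ci + co)/2 + u^2*(ci - co)/12 + O(u^3)
    out[small] <- zF * ((c_in - c_out) + us * (c_in + c_out) / 2 +
      us^2 * (c_in - c_out) / 12)
  }
  P * out
}

#' L-type Cav1.2 calcium current
#'
#' GHK calcium current scaled by permeability and the activation (`dL`) and
#' inactivation (`dF`) gates. Inward (negative) over the physiological
#' -45 to -20 mV window.
#'
#' @param V membrane potential (mV).
#' @param dL,dF activation and inactivation gate values in `[0, 1]`.
#' @param conc ion concentrations (uses `Ca_i`, `Ca_out`).
#' @param p channel parameters (uses `P_Ca`).
#' @param const physical constants.
#' @return Current in pA.
#' @export
i_ca <- function(V, dL, dF, conc, p, const = physical_constants()) {
  if (any(dL < 0 | dL > 1) || any(dF < 0 | dF > 1)) {
    stop("i_ca: gates must lie in [0, 1]")
  }
  ghk_current(V, const$z_Ca, p$P_Ca * dL * dF, conc$Ca_i, conc$Ca_out, const)
}

#' Delayed-rectifier Kv current (ohmic)
#'
#' `G * X_act * (V - E_K)`; used once per Kv species (Kv2.1, Kv1.5); the total
#' Kv current is their sum.
#'
#' @param V membrane potential (mV).
#' @param X_act activation gate in `[0, 1]`.
#' @param G maximal conductance (nS).
#' @param E_K potassium reversal potential (mV).
#' @return Current in pA.
#' @export
i_kv <- function(V, X_act, G, E_K) {
  if (any(X_act < 0 | X_act > 1)) stop("i_kv: gate must lie in [0, 1]")
  G * X_act * (V - E_K)
}

#' BK(Ca) alpha-beta1 current
#'
#' GHK potassium current scaled by `P_BKCa * N_BK / 8 * X_ab`. The
#' permeability is referenced to the default cluster size of 8 channels and
#' scales linearly with `N_BK`.
#'
#' @param V membrane potential (mV).
#' @param X_ab BK activation gate in `[0, 1]` (see [bk_activation_ss()]).
#' @param conc ion concentrations (uses `K_in`, `K_out`).
#' @param p channel parameters (uses `P_BKCa`, `N_BK`).
#' @param const physical constants.
#' @return Current in pA.
#' @export
i_bk <- function(V, X_ab, conc, p, const = physical_constants()) {
  if (any(X_ab < 0 | X_ab > 1)) stop("i_bk: gate must lie in [0, 1]")
  ghk_current(V, const$z_K, p$P_BKCa * (p$N_BK / 8) * X_ab,
              conc$K_in, conc$K_out, const)
}

#' BK(Ca) steady-state activation
#'
#' Boltzmann activation in voltage whose half-activation potential decreases
#' with the logarithm of junctional Ca2+, calibrated so that the activation
#' curves at 1, 10 and 100 uM junctional Ca2+ span the physiological range
#' and the 10 uM and 100 uM I-V curves nearly coincide at negative
#' potentials.
#'
#' @param V membrane potential (mV).
#' @param Ca_Jun junctional Ca2+ in uM (> 0).
#' @param p optional BK gate parameters (`bk_vh0` mV at 1 uM, `bk_slope_ca`
#'   mV per e-fold Ca, `bk_k` mV slope).
#' @return Open fraction in `[0, 1]`.
#' @export
bk_activation_ss <- function(V, Ca_Jun, p = NULL) {
  if (any(Ca_Jun <= 0)) stop("bk_activation_ss: Ca_Jun must be positive")
  vh0 <- if (is.null(p$bk_vh0)) 20 else p$bk_vh0
  s <- if (is.null(p$bk_slope_ca)) 17.4 else p$bk_slope_ca
  k <- if (is.null(p$bk_k)) 18 else p$bk_k
  vh <- vh0 - s * log(Ca_Jun)
  1 / (1 + exp(-(V - vh) / k))
}

#' BK(Ca) activation time constant
#'
#' Voltage-dependent bell-shaped time constant with an additive floor;
#' insensitive to junctional Ca2+.
#'
#' @param V membrane potential (mV).
#' @param p optional parameters (`bk_tau_scale` ms, `bk_tau_floor` ms).
#' @return Time constant in ms.
#' @export
bk_tau <- function(V, p = NULL) {
  sc <- if (is.null(p$bk_tau_scale)) 12 else p$bk_tau_scale
  fl <- if (is.null(p$bk_tau_floor)) 1.5 else p$bk_tau_floor
  sc / cosh(V / 40) + fl
}

#' Nonselective cation current (NSC)
#'
#' Linear, time-independent cation current permeable to Na+ and K+ with
#' permeability ratio P_Na:P_K = 0.9:1.3. The reversal potential is the
#' bi-ionic GHK voltage; the Na+ and K+ components are ohmic about it.
#'
#' @param V membrane potential (mV).
#' @param conc ion concentrations.
#' @param p channel parameters (uses `G_NaNSC`, `G_KNSC`).
#' @param const physical constants.
#' @return List with `I_NaNSC`, `I_KNSC`, `I_NSC` (pA) and `E_NSC` (mV).
#' @export
i_nsc <- function(V, conc, p, const = physical_constants()) {
  if (any(unlist(conc[c("Na_in", "Na_out", "K_in", "K_out")]) <= 0)) {
    stop("i_nsc: concentrations must be positive")
  }
  P_Na <- 0.9
  P_K <- 1.3
  E_NSC <- rtf_mv(const) * log(
    (P_K * conc$K_out + P_Na * conc$Na_out) /
      (P_K * conc$K_in + P_Na * conc$Na_in)
  )
  I_Na <- p$G_NaNSC * (V - E_NSC)
  I_K <- p$G_KNSC * (V - E_NSC)
  list(I_NaNSC = I_Na, I_KNSC = I_K, I_NSC = I_Na + I_K, E_NSC = E_NSC)
}

#' Sodium-potassium pump current
#'
#' `I_NaKmax * N1 * N2 * N0 * Npow` with Hill factors
#' `N1 = K_out^1.1 / (K_out^1.1 + Km_K^1.1)`,
#' `N2 = Na_in^1.7 / (Na_in^1.7 + Km_Na^1.7)`, the Luo-Rudy-style voltage
#' factor `N0`, and temperature scaling `Npow = Q10^((T - 309.2)/10)`.
#' Always outward (>= 0).
#'
#' @param V membrane potential (mV).
#' @param conc ion concentrations.
#' @param p channel parameters (`I_NaKmax`, `Km_NaK_K`, `Km_NaK_Na`, `Q10`,
#'   optionally `nak_voltage_variant` = "as_printed" (default, exponent
#'   -1.9*VF/RT in the second term) or "luo_rudy" (exponent -VF/RT)).
#' @param const physical constants.
#' @return Current in pA (>= 0).
#' @export
i_nak <- function(V, conc, p, const = physical_constants()) {
  vf <- V / rtf_mv(const)
  N1 <- conc$K_out^1.1 / (conc$K_out^1.1 + p$Km_NaK_K^1.1)
  N2 <- conc$Na_in^1.7 / (conc$Na_in^1.7 + p$Km_NaK_Na^1.7)
  slope <- if (identical(p$nak_voltage_variant, "luo_rudy")) 1.0 else 1.9
  N0 <- 1.0 / (1 + 0.1245 * exp(-0.1 * vf) +
    2.19e-3 * exp(conc$Na_out / 49.71) * exp(-slope * vf))
  Npow <- p$Q10^((const$T - 309.2) / 10)
  p$I_NaKmax * N1 * N2 * N0 * Npow
}

#' Sodium-calcium exchanger current
#'
#' `P_NCX * (Na_in^3 * Ca_out * phiF - Na_out^3 * Ca_i * phiR) /
#' (1 + 0.0003 * (Na_out^3 * Ca_i + Na_in^3 * Ca_out))` with
#' `phiF = exp(gamma*V*F/RT)`, `phiR = exp((gamma - 1)*V*F/RT)`.
#' Positive (outward) current corresponds to reverse-mode Ca2+ entry
#' (3 Na+ out / 1 Ca2+ in).
#'
#' @param V membrane potential (mV).
#' @param conc ion concentrations.
#' @param p channel parameters (`P_NCX`, `gamma_x`, optionally `k_sat_NCX`).
#' @param const physical constants.
#' @return Current in pA.
#' @export
i_ncx <- function(V, conc, p, const = physical_constants()) {
  vf <- V / rtf_mv(const)
  ksat <- if (is.null(p$k_sat_NCX)) 3e-4 else p$k_sat_NCX
  phiF <- exp(p$gamma_x * vf)
  phiR <- exp((p$gamma_x - 1) * vf)
  num <- conc$Na_in^3 * conc$Ca_out * phiF - conc$Na_out^3 * conc$Ca_i * phiR
  den <- 1 + ksat * (conc$Na_out^3 * conc$Ca_i + conc$Na_in^3 * conc$Ca_out)
  p$P_NCX * num / den
}

#' Plasma membrane Ca-ATPase current
#'
#' Hill (n = 2) saturating pump current `I_PMCAbar * Ca_i^2 /
#' (Ca_i^2 + Km_PMCA^2)`; Ca-extruding, outward positive.
#'
#' @param Ca_i cytosolic free Ca2+ (mM, >= 0).
#' @param p channel parameters (`I_PMCAbar`, `Km_PMCA`).
#' @return Current in pA (>= 0).
#' @export
i_pmca <- function(Ca_i, p) {
  if (any(Ca_i < 0)) stop("i_pmca: Ca_i must be non-negative")
  p$I_PMCAbar * Ca_i^2 / (Ca_i^2 + p$Km_PMCA^2)
}

#' Ohmic leak current
#'
#' `G * (V - E)`; one instance each for the Na+, K+ and Ca2+ background
#' currents.
#'
#' @param V membrane potential (mV).
#' @param G leak conductance (nS, >= 0).
#' @param E reversal potential (mV).
#' @return Current in pA.
#' @export
i_leak <- function(V, G, E) {
  if (any(G < 0)) stop("i_leak: conductance must be non-negative")
  G * (V - E)
}
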