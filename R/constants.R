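#' Physical constants for the myocyte model
#'
#' Returns the fixed physical constants used throughout the model. Temperature
#' defaults to 309.2 K (36 C), the reference temperature of the Na/K pump
#' Q10 factor, so that `Npow = 1` at default conditions.
#'
#' @param T_K absolute temperature in kelvin.
#' @return A list with elements `F` (Faraday constant, C/mol), `R` (gas
#'   constant, J/(mol K)), `T` (K), and ion valences `z_Ca`, `z_K`, `z_Na`.
#' @examples
#' const <- physical_constants()
#' const$R * const$T / const$F * 1000 # thermal voltage in mV, ~26.6
#' @export
physical_constants <- function(T_K = 309.2) {
  stopifnot(is.numeric(T_K), T_K > 0)
  list(F = 96485.332, R = 8.314462, T = T_K, z_Ca = 2L, z_K = 1L, z_Na = 1L)
}

#' Default ion concentrations
#'
#' Bulk intra/extracellular Na+ and K+ and the three-compartment Ca2+
#' concentrations, all in mM. The K+ pair is chosen so that the potassium
#' Nernst potential is -84 mV at the default temperature. Cytosolic free Ca2+
#' rests in the 100-300 nM band, SR Ca2+ in the 100-150 uM band, junctional
#' Ca2+ near 10 uM between sparks.
#'
#' @return A list with elements `Na_in`, `Na_out`, `K_in`, `K_out`, `Ca_i`,
#'   `Ca_out`, `Ca_SR`, `Ca_Jun` (all mM).
#' @export
default_concentrations <- function() {
  list(
    Na_in = 10, Na_out = 140,
    K_in = 140, K_out = 5.98,
    Ca_i = 1.5e-4, Ca_out = 2,
    Ca_SR = 0.120, Ca_Jun = 2e-4
  )
}

# thermal voltage RT/F in mV
rtf_mv <- function(const) 1000 * const$R * const$T / const$F
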