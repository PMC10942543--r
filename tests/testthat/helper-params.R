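# Shared fixtures: calibrated parameter sets tuned to the sex-specific
# resting potentials, built once per test run.
male_params <- tune_nsc_for_baseline(default_parameters("male"), -40)
female_params <- tune_nsc_for_baseline(default_parameters("female"), -30)
model_const <- physical_constants()
model_conc <- default_concentrations()

# a parameter set with every transmembrane pathway silenced (for noise and
# conservation oracles)
silent_params <- local({
  p <- default_parameters("male")
  for (nm in c("P_Ca", "G_Kv21", "G_Kv15", "P_BKCa", "G_NaNSC", "G_KNSC",
               "G_Nab", "G_Kb", "G_Cab", "I_NaKmax", "P_NCX", "I_PMCAbar")) {
    p$channels[[nm]] <- 0
  }
  p
})

# sealed-membrane configuration: internal Ca2+ fluxes active, all
# sarcolemmal Ca2+ pathways off (total Ca2+ must then be conserved)
sealed_ca_params <- local({
  p <- tune_nsc_for_baseline(default_parameters("male"), -40)
  for (nm in c("P_Ca", "G_Cab", "P_NCX", "I_PMCAbar")) p$channels[[nm]] <- 0
  p
})

# volume-weighted total Ca2+ (mol) including the buffered fraction
total_ca <- function(state, p) {
  v <- p$volumes
  v$Vol_cyt * (state[, "Ca_i"] + state[, "BUF_CAM"]) +
    v$Vol_SR * state[, "Ca_SR"] + v$Vol_Jun * state[, "Ca_Jun"]
}
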