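{
  "schema": "vsmsim-params-1",
  "units": {
    "voltage": "mV",
    "time": "ms",
    "current": "pA",
    "conductance": "nS",
    "concentration": "mM",
    "volume": "L",
    "capacitance": "pF"
  },
  "sex": "male",
  "temperature_K": 309.2,
  "concentrations_mM": {
    "Na_in": 10,
    "Na_out": 140,
    "K_in": 140,
    "K_out": 5.98,
    "Ca_i": 0.00015,
    "Ca_out": 2,
    "Ca_SR": 0.12,
    "Ca_Jun": 0.0002
  },
  "volumes": {
    "Vol_cyt": 1e-12,
    "Vol_SR": 5e-14,
    "Vol_Jun": 5e-15,
    "surface_area": 1.6e-05,
    "C_m": 16
  },
  "channels": {
    "P_Ca": 4.88912497347357e-06,
    "G_Kv21": 0.565779943051411,
    "G_Kv15": 1.47176379760165,
    "P_BKCa": 1.28499447665079e-05,
    "N_BK": 8,
    "G_NaNSC": 0.0914655977501866,
    "G_KNSC": 0.132116974528047,
    "G_Nab": 0.0053,
    "G_Kb": 0.008,
    "G_Cab": 0.000854683,
    "I_NaKmax": 2.3,
    "Km_NaK_K": 1.5,
    "Km_NaK_Na": 12,
    "Q10": 1.87,
    "P_NCX": 0.0001,
    "gamma_x": 0.35,
    "k_sat_NCX": 0.0003,
    "I_PMCAbar": 3.02085,
    "Km_PMCA": 0.000212186,
    "bk_vh0": 20,
    "bk_slope_ca": 17.4,
    "bk_k": 18,
    "bk_tau_scale": 12,
    "bk_tau_floor": 1.5
  },
  "gates": {
    "dL": {
      "x1": 0.923632012366331,
      "x2": 13,
      "x3": 0.0169169104045766,
      "x4": -13,
      "x5": 1
    },
    "dF": {
      "x1": 0.00195531943490418,
      "x2": -14,
      "x3": 0.142062607684043,
      "x4": 14,
      "x5": 15
    },
    "kv21": {
      "x1": 0.0258409632111917,
      "x2": 21.8441488806302,
      "x3": 0.0199887644047311,
      "x4": -21.8441488806302,
      "x5": 3
    },
    "kv15": {
      "x1": 0.102657145807701,
      "x2": 16,
      "x3": 0.00842661167235853,
      "x4": -16,
      "x5": 3
    }
  },
  "sr_fluxes": {
    "serca_vmax": 2.4e-06,
    "serca_km": 0.0002,
    "ryr_nu_rel": 0.0001,
    "ryr_nu_leak": 1.35e-06,
    "ryr_thr": 0.118,
    "ryr_k": 0.0005,
    "ryr_kjun": 0.0018,
    "ryr_hill": 4,
    "ryr_tau": 5,
    "k_JunCyt": 0.0006
  },
  "buffer": {
    "k_BUFon": 500,
    "k_BUFoff": 1,
    "BUF_T": 0.05
  },
  "clamp_ions": true
}
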