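# vsmsim

Simulation of electrical activity and Ca²⁺ signaling in mesenteric
arterial smooth muscle myocytes, with **male and female parameter sets**.
The package is aimed at vascular physiologists and modelers who want to
ask how sex-specific differences in Kv2.1 and Ca_V1.2 channel expression
propagate to membrane potential, cytosolic Ca²⁺, and the response to
clinically used Ca²⁺ channel blockers such as nifedipine — at the level of
a single cell or an idealized 1D vessel.

## The model

A Hodgkin–Huxley-type membrane model with 11 transmembrane currents,

dV/dt = −(I_Kv1.5 + I_Kv2.1 + I_BKCa + I_K,b + I_Ca + I_PMCA + I_Ca,b +
I_NCX + I_NSC + I_NaK + I_Na,b)/C_m,

coupled to three-compartment Ca²⁺ dynamics (cytosol, sarcoplasmic
reticulum, SR–sarcolemma junction) with calmodulin buffering, SERCA
uptake, and a deterministic RyR spark oscillator that drives BK_Ca
STOCs and the characteristic transient hyperpolarizations (THs) of these
cells. L-type and BK currents use the Goldman–Hodgkin–Katz flux form;
every voltage-dependent gate follows the five-parameter rate law
α = x₁e^{V/x₂}, β = x₃e^{V/x₄}, τ = 1/(α+β) + x₅. Stochastic runs add
Gaussian white noise to dV/dt and the SR load via Euler–Maruyama
integration (compiled, counter-based RNG with per-cell substreams). A 1D
vessel couples N cells through gap-junction resistance (71.4 Ω·cm²) via
the finite-difference cable equation. Intravascular pressure is
represented by tuning the nonselective cation conductance to per-sex
baseline potentials.

The male/female parameter sets are calibrated at build time from
published anchor values (Kv2.1 peak and steady-state currents, the
Kv1.5:Kv2.1 contribution split, steady L-type current, resting
potentials); `calibrate_sex_models()` reproduces them and reports each
anchor's achieved value. See the methods vignette
(`vignettes/model-methods.Rmd`) for the full model description.

## Worked example

```r
library(vsmsim)

# calibrated male cell, resting at -40 mV
male <- tune_nsc_for_baseline(default_parameters("male"), -40)

# steady-state currents at a clamped -40 mV
cur <- steady_currents(male, -40)
round(c(I_Kv15 = cur$I_Kv15, I_Kv21 = cur$I_Kv21, I_Ca = cur$I_Ca), 3)
#> I_Kv15 I_Kv21   I_Ca
#>  4.914  0.800 -0.500

kv_contributions(male, -40)
#> pct_Kv15 pct_Kv21
#>       86       14

# a noisy 30 s current-clamp run: spontaneous transient hyperpolarizations
tr <- simulate(male, 30000, noise_config(seed = 5), discard_ms = 8000)
round(c(V_baseline = median(tr$state[, "V"]), TH_Hz = th_frequency(tr)), 2)
#> V_baseline      TH_Hz
#>     -40.44       1.33

# nifedipine (65% L-type block) pulls cytosolic Ca down to ~85 nM
blocked <- apply_drug(male, drug_block(fraction = 0.65))
round(find_equilibrium(blocked)$state[["Ca_i"]] * 1e6, 1) # nM
#> 82.3
```

The first block prints the steady −40 mV operating point: 0.5 pA of
sustained L-type Ca²⁺ influx opposed by a total Kv current that is 86%
Kv1.5 in the male cell (the female model gives 77% Kv2.1 instead). The
noisy run shows the ~−40 mV male baseline interrupted by 10–15 mV
transient hyperpolarizations at ~1.3 Hz, each triggered by an SR Ca²⁺
spark activating the BK_Ca cluster. The last line is the post-drug
cytosolic Ca²⁺ baseline; running the same block on the female model lands
within a few nM of the same value, although the female cell starts ~15 nM
higher — the convergence that underlies the larger female response to
Ca²⁺ channel blockers.

A vessel-level experiment:

```r
female <- params_at_pressure(default_parameters("female"), 80) # 80 mmHg
vt <- simulate_vessel(female, cable_params(N_cells = 50), 25000,
                      noise_config(seed = 1, dt = 0.05), discard_ms = 12000)
round(vt$summary[["mean_Ca_i"]] * 1e6, 1) # vessel-averaged Ca_i in nM
#> 150
```

A command-line wrapper over the same functions is in
`inst/cli/vsmsim.R` (subcommands `simulate-cell`, `simulate-vessel`,
`fit-gate`, `sensitivity`, `iv`).

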