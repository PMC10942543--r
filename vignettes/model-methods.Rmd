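---
title: "Modeling sex-specific electrophysiology of arterial myocytes with vsmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sex-specific electrophysiology of arterial myocytes with vsmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmsim)
```

## The model

`vsmsim` implements a Hodgkin–Huxley-type model of a mesenteric arterial
smooth muscle myocyte with male and female parameterizations. The membrane
potential obeys

$$\frac{dV}{dt} = -\frac{I_{ion}}{C_m}, \qquad
I_{ion} = I_{Kv1.5} + I_{Kv2.1} + I_{BK_{Ca}} + I_{K,b} + I_{Ca}
 + I_{PMCA} + I_{Ca,b} + I_{NCX} + I_{NSC} + I_{NaK} + I_{Na,b},$$

with outward current positive and $C_m = 16$ pF (cylindrical cell of
surface area $1.6\times10^{-5}$ cm² at 1 µF/cm²). The L-type Ca$_V$1.2 and
BK$_{Ca}$ currents use the Goldman–Hodgkin–Katz constant-field form with a
series expansion across the removable singularity at $V = 0$; the delayed
rectifiers Kv1.5 and Kv2.1, the nonselective cation (NSC) current and the
three background leaks are ohmic; the Na/K pump uses Hill factors
(exponents 1.1 and 1.7) with a Luo–Rudy-style voltage factor and a Q10
anchor at 309.2 K; the Na/Ca exchanger follows the ten Tusscher
formulation with energy-barrier position $\gamma = 0.35$ and saturation
factor $3\times10^{-4}$; the plasma-membrane Ca pump is a Hill $n=2$
extruder.

Every voltage-dependent gate follows the five-parameter rate law
$\alpha = x_1 e^{V/x_2}$, $\beta = x_3 e^{V/x_4}$,
$\tau = 1/(\alpha+\beta) + x_5$, $n_\infty = \alpha/(\alpha+\beta)$, so a
gate's steady state is a Boltzmann whose midpoint and slope are set by
$x_3/x_1$ and $1/x_4 - 1/x_2$, and $x_5$ floors the time constant.
`boltzmann_rate_params()` constructs the $x_i$ for a requested midpoint,
slope and $\tau$ peak.

Calcium is compartmentalized into the cytosol (1 pL), the sarcoplasmic
reticulum (5% of cytosolic volume) and a junctional domain (1%), with
first-order calmodulin buffering in the cytosol. The cytosolic balance
couples the Ca-carrying membrane currents as
$-(I_{Ca} + I_{Ca,b} + I_{PMCA} - 2 I_{NCX})/(2 F V_{cyt})$: PMCA carries
one Ca²⁺ out per two elementary charges, and a positive (outward) NCX
current is reverse-mode operation importing one Ca²⁺ per elementary
charge. SERCA uptake is a Hill $n=1$ pump; RyR release into the junction
is $(\nu_{leak} + \nu_{rel}\, r)(Ca_{SR} - Ca_{Jun})$ with the gated open
fraction $r$ relaxing toward
$\phi(Ca_{SR})\,\psi(Ca_{Jun})$ — a steep sigmoid in SR load (release
probability correlates with SR load) times a Hill-4 Ca-induced-Ca-release
term in junctional Ca²⁺.

### The spark–STOC oscillator

The RyR description is deterministic but built as a relaxation oscillator
so that the cell reproduces the spark/STOC cycle: SERCA loads the SR until
the load threshold (118 µM, width 0.5 µM) is crossed; regenerative CICR
then dumps SR Ca²⁺ into the junction, which rises into the 10–20 µM band,
activates the BK$_{Ca}$ cluster (a 10–25 pA STOC), and hyperpolarizes the
membrane by 10–15 mV; SR depletion through the threshold terminates the
spark and SERCA reloads over ~0.7 s. Two conditions shaped the parameter
choices, both derived from the fast-subsystem stability analysis:

* *ignition near threshold* requires the resting junctional Ca²⁺ (set by
  the leak $\nu_{leak}$ and the junction–cytosol transfer rate
  $k_{JunCyt}$) to sit on the steep rising part of the CICR Hill curve;
* *instability of the smooth-release balance* requires the CICR
  half-point (1.8 µM) to exceed the junctional Ca²⁺ forced through the
  junction by steady SERCA throughput, for both the male and the more
  Ca-loaded female operating points.

Violating either condition produces a stable continuous-release state
(no sparks) or rare giant sparks with unphysiological SR overload; the
shipped values satisfy both for the male (−40 mV) and female (−30 mV)
baselines. With these values the deterministic male cell fires at
~1.3 Hz with the noisy-run transient-hyperpolarization frequency inside
the experimentally reported 1–2.8 Hz band; the female cell fires smaller,
more frequent events on its more depolarized baseline.

## Sex-specific calibration

The printed anchors used by `calibrate_sex_models()` are: the Kv2.1
voltage-clamp peak at +40 mV (68.8 pA male, 226.42 pA female), the
steady-state Kv2.1 currents at −40/−30 mV (0.8/2.34 pA male, 3.3/9.2 pA
female), the Kv1.5:Kv2.1 contribution split at −40 mV (86:14 male, 23:77
female), the steady L-type current at −40 mV (0.5 pA male, 0.65 pA
female), and the resting potentials (−40/−30 mV). The Kv2.1 Boltzmann
midpoint and slope are solved exactly from the two steady-state-to-peak
ratios (nested scalar root-finding), the conductance from the peak, the
Kv1.5 conductance from the split, and the L-type permeability from the
−40 mV window current. Kv2.1 activation kinetics are set slower in the
female model (τ peak 75 ms vs 25 ms), consistent with the reported
sex difference; Kv1.5 kinetics and the Ca$_V$1.2 gating curves are
shared between sexes.

Constants not printed anywhere were chosen once as follows and are not
per-sex: the extrusion set (PMCA maximum 3.02 pA, $K_m$ 212 nM, Ca leak
conductance $8.5\times10^{-4}$ nS, NCX scale $10^{-4}$) was solved
numerically so that (i) 65% L-type block at a −40 mV baseline drives both
sexes to a common ~85 nM cytosolic Ca²⁺ baseline, and (ii) the same block
at the 80 mmHg vessel operating points (−45 mV male, −35 mV female)
reduces Ca²⁺ by ~22% and ~38%. The resulting pre-drug baselines
(115 nM male, 130 nM female at −40 mV) fall in the physiological
100–300 nM band and differ by the reported ~15 nM.

Bulk cytosolic Na⁺ and K⁺ are clamped by default: their turnover time is
hours, and a free steady state would drift the K⁺ equilibrium potential
off its −84 mV anchor. The dynamic balance equations (3:2 pump
stoichiometry, 3:1 exchanger) are implemented and tested, and a switch
(`clamp_ions = FALSE`) enables them; over 1 s the two modes agree within
0.5 mV.

## Steady-state readouts

Steady-state quantities are computed from the clamped system by nested
scalar root-finding rather than long forward integration: at clamped $V$
the gates sit at $n_\infty(V)$ and cytosolic Ca²⁺ solves the scalar
sarcolemmal balance $I_{Ca} + I_{Ca,b} + I_{PMCA} - 2 I_{NCX} = 0$
(`fixed_state()`, `baseline_state()`, `steady_currents()`). In the
oscillatory regime the true fixed point is unstable and its SR load is
unphysiological, so operating-point readouts use the *inter-spark
baseline state* (SR just below the release threshold, junction at the
leak balance); the two states carry identical Kv, L-type, pump and
exchanger currents, and forward integration converges to the same
time-averaged values. `tune_nsc_for_baseline()` rescales the Na⁺ and K⁺
NSC conductances jointly so the total current vanishes at a requested
baseline potential — the model's proxy for pressure-induced
depolarization.

## Stochastic integration

Noise enters as Gaussian white-noise terms on $dV/dt$ (σ$_V$ = 0.35
mV·ms$^{-1/2}$) and on the SR Ca²⁺ update (σ$_{SR}$ = 4×10⁻⁶
mM·ms$^{-1/2}$), integrated by Euler–Maruyama
($x \leftarrow x + f\,\Delta t + \sigma\,\mathcal{N}(0,1)\sqrt{\Delta t}$,
all other states forward Euler). The σ values are free parameters
calibrated so that baseline fluctuations are a few mV, as in
current-clamp records. With both σ at zero the scheme is exactly forward
Euler. The default step is 0.01 ms for single cells (fastest time
constants are a few ms) and 0.05 ms for vessel runs; halving the step
changes quiescent steady-state voltage by under 0.1 mV. The noise
generator is a counter-based splitmix64 stream with Box–Muller pairs; one
master seed derives per-cell substreams deterministically, so vessel cell
$i$ is bitwise reproducible by a single-cell run on substream $i$.
Gates are clamped to $[0,1]$ after each step. Noise is never applied to a
clamped command potential.

## The 1D vessel

`simulate_vessel()` couples $N$ identical cells through the
finite-difference cable term
$\frac{a}{4(R_{myo} + R_g/\Delta x)} \frac{V_{i-1} - 2V_i +
V_{i+1}}{\Delta x^2}$ (per unit membrane capacitance), with sealed
(no-flux) ends, radius 5 µm, $\Delta x$ = 100 µm, $R_{myo}$ = 150 Ω·cm
and $R_g$ = 71.4 Ω·cm² — an effective inter-cell coupling of ~2.7 nS,
several times the resting membrane conductance, which is what produces
the observed electrotonic smoothing of per-cell hyperpolarizations.
Stochastic fluctuations are required in vessel runs for the cable to
average over desynchronized spark cycles; the deterministic mode is
retained for testing (a uniform deterministic cable is invariant and
reproduces the single-cell trajectory exactly).

Pressure is represented through the NSC conductance: `pressure_map()`
prescribes per-sex baseline potentials (piecewise-linear through −52/−45/
−42.5 mV for male and −42/−35/−31 mV for female at 20/80/120 mmHg), and
`params_at_pressure()` retunes the NSC conductance to that baseline. The
80 mmHg anchors are the sharp-electrode values; the 120 mmHg anchors were
calibrated against the reported percent reductions under L-type block
(25% male; the female 45% value is discussed under Limitations). Vessel
summaries are time-and-space averages over the final window of at least
13 s with the first 12 s discarded; production-scale cables (N = 400) and
desk-scale cables (N = 50) give summary statistics within a few percent
because cells are statistically exchangeable beyond the ~2-cell
electrotonic length.

## Sensitivity analysis

`sensitivity_analysis()` perturbs the 11 maximal conductances /
permeabilities / transport maxima with log-normal scale factors (median
1, distribution SD 0.1 — the stated SD is read as the SD of the
distribution itself, not of the underlying normal; at this scale the two
differ by under 1%). Kinetic parameters are never perturbed. Outputs
(baseline potential, cytosolic Ca²⁺) are computed from the deterministic
equilibrium of each population member, and standardized (z-scored)
outputs are regressed on standardized log scale factors by ordinary least
squares. The default population is 300 members; each member costs only a
root-finding cascade, so the analysis runs in seconds. Coefficients
reproduce the expected physiology: the NSC scale depolarizes, the Kv
scales hyperpolarize, with Kv1.5 dominant in the male model and Kv2.1 in
the female model.

## Gating-curve fitting

`fit_gate()` minimizes a range-normalized least-squares objective over
whichever summary curves are supplied (steady-state activation, time
constants, peak I–V) using Nelder–Mead with randomized restarts that
perturb the incumbent by under 10% multiplicatively; the best restart is
kept and the improvement trace is monotone. Because the five parameters
are not identifiable from the curves (only the Boltzmann midpoint/slope
and the τ profile are), the contract is curve reproduction, not parameter
recovery: on noise-free pseudo-data the fitted curves match the
generating curves to below 10⁻⁶ RMS. `make_pseudo_data()` generates
seeded multiplicative-noise fixtures for this workflow.

## Numerical choices and degenerate inputs

* GHK evaluations switch to a 3-term series for $|zVF/RT| < 10^{-4}$;
  the ±1 nV values agree with the analytic $V = 0$ limit to 6 digits.
* Root brackets: cytosolic Ca²⁺ balance on [10⁻⁷, 0.02] mM; baseline
  voltage search on [−80, −10] mV; both are sign-changing across the
  physiological range for all shipped parameter sets.
* Gates are hard-clamped to $[0,1]$; non-finite states abort integration
  with the failure time.
* Channel counts round half away from zero; a zero single-channel
  current is an error, as are gates outside $[0,1]$, non-positive
  concentrations, and unknown parameter or current names.
* Transient hyperpolarizations are detected as downward crossings of
  5 mV below a 2 s running-median baseline with a 100 ms refractory
  period; the detector is invariant to additive offsets and to doubling
  the sampling rate.

## What the synthetic data do and do not show

The pseudo-data generator and the simulation fixtures emulate summary
curves and traces with multiplicative Gaussian noise on an exact forward
model. Real patch-clamp data carry correlated errors (seal drift, series
resistance, junction-potential offsets, cell-to-cell variability) that
these fixtures do not model, so passing tests demonstrate correctness of
the fitting and analysis machinery, not robustness to every experimental
artifact. Likewise the vessel is an idealized homogeneous cable: no
endothelium, no receptor signaling, no contraction mechanics, murine
parameter provenance.

## Known limitations

* The female vessel reduction under L-type block saturates near 40%
  rather than the reported 45% at 120 mmHg: with a shared extrusion
  system, the reduction is capped by how far the pre-drug Ca²⁺ can rise
  along the window current, which peaks near −30 mV. Matching 45% would
  require a sex-specific Ca-handling difference the source data do not
  constrain.
* The L-type I–V peak ratio between sexes is 1.3 (fixed by the −40 mV
  steady-current anchors with shared gating); the separately reported
  "40% smaller" peak I–V is not reproduced exactly.
* Ca²⁺-dependent L-type inactivation and Kv2.1 inactivation are omitted
  (negligible in the sub-µM, slow-inactivation regime the cell operates
  in).
* The deterministic spark oscillator represents the average behavior of
  one junctional unit; spark amplitude/frequency heterogeneity across
  junctions is folded into the two noise terms.
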