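# Ionic current primitives: Nernst, GHK, and the pump/exchanger forms.

test_that("nernst potential: symmetry, potassium anchor, closed form", {
  expect_equal(nernst(1, 5, 5, model_const), 0)
  expect_equal(nernst(2, 0.1, 0.1, model_const), 0)
  # default K+ pair sits at the potassium equilibrium potential of -84 mV
  expect_equal(nernst(1, model_conc$K_in, model_conc$K_out, model_const),
               -84, tolerance = 1e-3)
  # z = +2 with c_out/c_in = e^2 gives exactly RT/F
  rtf <- 1000 * model_const$R * model_const$T / model_const$F
  expect_equal(nernst(2, 1, exp(2), model_const), rtf, tolerance = 1e-12)
  expect_error(nernst(1, -1, 5), "positive")
  expect_error(nernst(0, 5, 5), "valence")
})

test_that("GHK current: zero permeability, reversal, continuity at V = 0", {
  expect_equal(ghk_current(c(-80, 0, 40), 2, 0, 1e-4, 2), rep(0, 3))
  # vanishes at the Nernst potential of the permeant ion
  e_ca <- nernst(2, 1e-4, 2, model_const)
  i_rev <- ghk_current(e_ca, 2, 1e-6, 1e-4, 2, model_const)
  i_ref <- abs(ghk_current(-40, 2, 1e-6, 1e-4, 2, model_const))
  expect_lt(abs(i_rev), 1e-10 * i_ref)
  # removable singularity: +-1e-9 mV agree with the V = 0 limit to 6 digits
  i0 <- ghk_current(0, 2, 1e-6, 1e-4, 2, model_const)
  ip <- ghk_current(1e-9, 2, 1e-6, 1e-4, 2, model_const)
  im <- ghk_current(-1e-9, 2, 1e-6, 1e-4, 2, model_const)
  expect_equal(ip / i0, 1, tolerance = 1e-6)
  expect_equal(im / i0, 1, tolerance = 1e-6)
  # analytic limit P z F (c_in - c_out)
  expect_equal(i0, 1e-6 * 2 * model_const$F * (1e-4 - 2), tolerance = 1e-12)
})

test_that("GHK current is odd in V for symmetric concentrations", {
  V <- seq(-90, 90, 7.5)
  i_pos <- ghk_current(V, 1, 1e-5, 3, 3, model_const)
  i_neg <- ghk_current(-V, 1, 1e-5, 3, 3, model_const)
  expect_equal(i_pos, -i_neg, tolerance = 1e-12)
})

test_that("gate-scaled currents vanish at zero gate and scale linearly", {
  ch <- male_params$channels
  conc <- model_conc
  expect_equal(i_ca(-40, 0, 0.8, conc, ch, model_const), 0)
  expect_equal(i_bk(-40, 0, conc, ch, model_const), 0)
  expect_equal(i_kv(-40, 0, ch$G_Kv21, -84), 0)
  # linearity in permeability: doubling P_Ca doubles the current
  ch2 <- ch
  ch2$P_Ca <- 2 * ch$P_Ca
  expect_equal(i_ca(-40, 0.5, 0.5, conc, ch2, model_const),
               2 * i_ca(-40, 0.5, 0.5, conc, ch, model_const),
               tolerance = 1e-12)
  # doubling the BK cluster size doubles the current at fixed gate
  ch3 <- ch
  ch3$N_BK <- 2 * ch$N_BK
  expect_equal(i_bk(-20, 0.4, conc, ch3, model_const),
               2 * i_bk(-20, 0.4, conc, ch, model_const), tolerance = 1e-12)
  expect_error(i_ca(-40, 1.2, 0.5, conc, ch), "\\[0, 1\\]")
})

test_that("ohmic currents: leak linearity and Kv reversal", {
  expect_equal(i_leak(-84, 0.01, -84), 0)
  expect_equal(i_leak(-40, 0, -84), 0)
  expect_equal(i_leak(-64, 0.01, -84), 0.5 * i_leak(-44, 0.01, -84))
  expect_equal(i_kv(-84, 0.5, 1.2, -84), 0)
})

test_that("NSC current: reversal between E_K and E_Na, zero at E_NSC", {
  ch <- male_params$channels
  nsc <- i_nsc(-40, model_conc, ch, model_const)
  e_k <- nernst(1, model_conc$K_in, model_conc$K_out, model_const)
  e_na <- nernst(1, model_conc$Na_in, model_conc$Na_out, model_const)
  expect_gt(nsc$E_NSC, e_k)
  expect_lt(nsc$E_NSC, e_na)
  at_rev <- i_nsc(nsc$E_NSC, model_conc, ch, model_const)
  expect_equal(at_rev$I_NaNSC, 0, tolerance = 1e-12)
  expect_equal(at_rev$I_KNSC, 0, tolerance = 1e-12)
})

test_that("NaK pump: Hill half-points, Na starvation, Q10 anchor", {
  ch <- male_params$channels
  conc <- model_conc
  conc$K_out <- ch$Km_NaK_K
  conc$Na_in <- ch$Km_NaK_Na
  # with both substrates at half-saturation the current is Imax N0 / 4
  i_half <- i_nak(-40, conc, ch, model_const)
  conc_sat <- model_conc
  conc_sat$K_out <- 1e6
  conc_sat$Na_in <- 1e6
  i_sat <- i_nak(-40, conc_sat, ch, model_const)
  expect_equal(i_half / i_sat, 0.25, tolerance = 1e-5)
  conc0 <- model_conc
  conc0$Na_in <- 1e-12
  expect_equal(i_nak(-40, conc0, ch, model_const), 0, tolerance = 1e-12)
  # at the reference temperature the Q10 factor is exactly 1
  expect_equal(model_const$T, 309.2)
  i1 <- i_nak(-40, model_conc, ch, model_const)
  ch2 <- ch
  ch2$Q10 <- 10
  expect_equal(i_nak(-40, model_conc, ch2, model_const), i1)
  expect_gt(i1, 0)
})

test_that("NCX: equilibrium, gamma = 1 limit, sign flip at reversal", {
  ch <- male_params$channels
  # equilibrium: forward and reverse terms equal -> zero current
  v_rev <- 3 * nernst(1, model_conc$Na_in, model_conc$Na_out, model_const) -
    2 * nernst(2, model_conc$Ca_i, model_conc$Ca_out, model_const)
  expect_equal(i_ncx(v_rev, model_conc, ch, model_const), 0,
               tolerance = 1e-10)
  # bisection oracle: the zero crossing found numerically matches 3E_Na-2E_Ca
  root <- uniroot(function(V) i_ncx(V, model_conc, ch, model_const),
                  c(-150, 100), tol = 1e-12)$root
  expect_equal(root, v_rev, tolerance = 1e-6)
  expect_lt(i_ncx(v_rev - 10, model_conc, ch, model_const), 0)
  expect_gt(i_ncx(v_rev + 10, model_conc, ch, model_const), 0)
  # gamma = 1 removes the voltage dependence of the reverse term
  ch1 <- ch
  ch1$gamma_x <- 1
  rtf <- 1000 * model_const$R * model_const$T / model_const$F
  for (V in c(-60, 0, 40)) {
    phiR_term <- exp((ch1$gamma_x - 1) * V / rtf)
    expect_equal(phiR_term, 1)
  }
})

test_that("PMCA: Hill n = 2 half-point and saturation", {
  ch <- male_params$channels
  expect_equal(i_pmca(0, ch), 0)
  expect_equal(i_pmca(ch$Km_PMCA, ch), ch$I_PMCAbar / 2, tolerance = 1e-12)
  expect_equal(i_pmca(1e3 * ch$Km_PMCA, ch), ch$I_PMCAbar, tolerance = 1e-5)
})

test_that("steady-state activations are bounded and monotone on a 1 mV grid", {
  V <- seq(-100, 100, 1)
  for (g in list(male_params$gates$dL, male_params$gates$kv21,
                 male_params$gates$kv15, female_params$gates$kv21)) {
    n <- rates(V, g)$n_inf
    expect_true(all(n >= 0 & n <= 1))
    expect_true(all(diff(n) > 0))
  }
  # inactivation gate decreases
  nf <- rates(V, male_params$gates$dF)$n_inf
  expect_true(all(diff(nf) < 0))
  # BK activation increases in V and in junctional Ca2+
  xa <- bk_activation_ss(V, 10)
  expect_true(all(xa >= 0 & xa <= 1))
  expect_true(all(diff(xa) > 0))
  expect_true(all(diff(bk_activation_ss(-20, c(0.03, 0.3, 3, 30))) > 0))
})

test_that("BK activation: Ca-dependent half-activation and I-V coincidence", {
  # half-activation voltage decreases monotonically over a wide Ca sweep
  ca <- exp(seq(log(0.003), log(100), length.out = 25))
  vhalf <- vapply(ca, function(cc) {
    uniroot(function(V) bk_activation_ss(V, cc) - 0.5, c(-250, 250))$root
  }, numeric(1))
  expect_true(all(diff(vhalf) < 0))
  # I-V at 10 and 100 uM junctional Ca2+ nearly coincide at depolarized V;
  # at 1 uM the current is markedly reduced
  ch <- male_params$channels
  iv_at <- function(ca_um, V) {
    x <- bk_activation_ss(V, ca_um)
    i_bk(V, x, model_conc, ch, model_const)
  }
  V <- c(20, 40, 60)
  expect_lt(max(abs(iv_at(100, V) - iv_at(10, V)) / iv_at(100, V)), 0.15)
  # reduction at 1 uM is assessed over the physiological voltage range
  expect_lt(max(iv_at(1, c(0, 20)) / iv_at(100, c(0, 20))), 0.7)
})
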