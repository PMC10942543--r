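# Three-compartment Ca2+ dynamics: fluxes, conservation, buffering.

test_that("flux primitives: trivial zeros and signs", {
  sr <- male_params$sr
  expect_equal(j_serca(0, NA, sr), 0)
  expect_equal(j_serca(sr$serca_km, NA, sr), sr$serca_vmax / 2,
               tolerance = 1e-12)
  expect_equal(j_ryr(0.12, 1e-4, 0, sr), sr$ryr_nu_leak * (0.12 - 1e-4))
  expect_gt(j_ryr(0.12, 1e-4, 0.5, sr), 0)
  expect_equal(j_jun_cyt(2e-4, 2e-4, sr), 0)
  expect_gt(j_jun_cyt(5e-4, 2e-4, sr), 0)
  expect_error(j_ryr(0.12, 1e-4, 1.5, sr), "\\[0, 1\\]")
})

test_that("ca_rhs: zero fluxes give zero derivatives; buffer equilibrium", {
  p <- male_params
  Kd <- p$buffer$k_BUFoff / p$buffer$k_BUFon
  ca <- 1.5e-4
  st <- list(Ca_i = ca, Ca_SR = 0.12, Ca_Jun = ca, ryr_state = 0,
             BUF_CAM = p$buffer$BUF_T * ca / (ca + Kd))
  zero_cur <- list(I_Ca = 0, I_Cab = 0, I_PMCA = 0, I_NCX = 0)
  p0 <- p
  p0$sr$serca_vmax <- 0
  p0$sr$ryr_nu_leak <- 0
  d <- ca_rhs(st, zero_cur, p0)
  expect_equal(unname(unlist(d)), rep(0, 4), tolerance = 1e-18)
  # buffer at equilibrium contributes nothing even with fluxes on
  d2 <- ca_rhs(st, zero_cur, p)
  expect_equal(d2$dBUF_CAM, 0, tolerance = 1e-18)
})

test_that("volume-weighted total Ca2+ is conserved with a sealed membrane", {
  p <- sealed_ca_params
  st <- initial_state(p)
  tr <- simulate(p, 5000, noise_config(0, 0, 1, 0.01), state = st,
                 discard_ms = 0, sample_every_ms = 10)
  tot <- total_ca(tr$state, p)
  drift <- abs(tot[length(tot)] - tot[1]) / tot[1]
  # relative drift below 1e-6 per simulated second (5 s run)
  expect_lt(drift / 5, 1e-6)
  # the run is not trivial: internal fluxes moved Ca between compartments
  expect_gt(max(tr$state[, "Ca_Jun"]) / min(tr$state[, "Ca_Jun"]), 1.5)
})

test_that("isolated junction relaxes exponentially at rate k_JunCyt", {
  # closed-form oracle: with RyR sealed and Ca_i pinned, the junction obeys
  # dCa_Jun/dt = -(Vcyt/VJun) k (Ca_Jun - Ca_i)
  p <- male_params
  p$sr$ryr_nu_rel <- 0
  p$sr$ryr_nu_leak <- 0
  ratio <- p$volumes$Vol_cyt / p$volumes$Vol_Jun
  k_eff <- ratio * p$sr$k_JunCyt
  st <- as.list(initial_state(p))
  st$Ca_Jun <- 5e-3
  times <- seq(0, 30, 0.5)
  num <- vapply(times, function(tt) {
    st$Ca_i + (5e-3 - st$Ca_i) * exp(-k_eff * tt)
  }, numeric(1))
  # numeric forward integration of the same ODE
  x <- 5e-3
  dt <- 1e-4
  sim <- c(x)
  for (tt in times[-1]) {
    for (i in seq_len(0.5 / dt)) x <- x + dt * (-k_eff * (x - st$Ca_i))
    sim <- c(sim, x)
  }
  expect_equal(sim, num, tolerance = 1e-3)
  # and the model's flux term matches the oracle's right-hand side
  d <- ca_rhs(st, list(I_Ca = 0, I_Cab = 0, I_PMCA = 0, I_NCX = 0), p)
  expect_equal(d$dCa_Jun, -k_eff * (st$Ca_Jun - st$Ca_i), tolerance = 1e-12)
})

test_that("Na/K bulk fluxes: stoichiometry and clamped-mode agreement", {
  p <- male_params
  cur <- list(I_Kv21 = 0, I_Kv15 = 0, I_BK = 0, I_Kb = 0, I_KNSC = 0,
              I_NCX = 0, I_Nab = 0, I_NaNSC = 0, I_NaK = 1.7)
  d <- na_k_rhs(cur, p)
  # 3 Na+ out / 2 K+ in per pump cycle
  expect_equal(d$dNa_in / d$dK_in, -3 / 2, tolerance = 1e-12)
  expect_lt(d$dNa_in, 0)
  # dynamic bulk ions drift slowly: 1 s free-running trace stays within
  # 0.5 mV of the clamped-ion trace
  pd <- p
  pd$clamp_ions <- FALSE
  st <- initial_state(p)
  trc <- simulate(p, 1000, noise_config(0, 0, 1, 0.01), state = st,
                  discard_ms = 0, sample_every_ms = 1)
  trd <- simulate(pd, 1000, noise_config(0, 0, 1, 0.01), state = st,
                  discard_ms = 0, sample_every_ms = 1)
  expect_lt(max(abs(trc$state[, "V"] - trd$state[, "V"])), 0.5)
})

test_that("SR load cycles within the physiological band at rest", {
  tr <- simulate(male_params, 15000, noise_config(0, 0, 1, 0.02),
                 state = initial_state(male_params), discard_ms = 5000,
                 sample_every_ms = 5)
  sr_um <- tr$state[, "Ca_SR"] * 1e3
  expect_gt(min(sr_um), 100)
  expect_lt(max(sr_um), 150)
  # buffered calmodulin stays within [0, BUF_T]
  expect_true(all(tr$state[, "BUF_CAM"] >= 0))
  expect_true(all(tr$state[, "BUF_CAM"] <= male_params$buffer$BUF_T))
})
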