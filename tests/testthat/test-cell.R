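# Full single-cell system: derivatives, integrators, steady states.

test_that("per-current values sum exactly to the I_ion used for dV/dt", {
  st <- initial_state(male_params)
  d <- derivatives(st, male_params)
  cur <- d$currents
  manual <- cur$I_Kv15 + cur$I_Kv21 + cur$I_BK + cur$I_Kb + cur$I_Ca +
    cur$I_PMCA + cur$I_Cab + cur$I_NCX + cur$I_NSC + cur$I_NaK + cur$I_Nab
  expect_identical(cur$I_ion, manual)
  expect_equal(d$dstate[["V"]], -cur$I_ion / male_params$volumes$C_m)
})

test_that("compiled and reference derivatives agree to near machine precision", {
  for (p in list(male_params, female_params)) {
    st <- initial_state(p)
    st[["Ca_Jun"]] <- 8e-3 # mid-spark
    st[["X_ab"]] <- 0.2
    for (vclamp in c(FALSE, TRUE)) {
      dR <- derivatives(st, p, if (vclamp) "voltage_clamp" else
        "current_clamp", V_cmd = if (vclamp) st[["V"]] else NULL)$dstate
      dC <- vsmsim:::cpp_derivatives(st, vsmsim:::.flatten_params(p), vclamp)$dstate
      expect_lt(max(abs(dR - dC) / (abs(dR) + 1e-12)), 1e-10)
    }
  }
})

test_that("voltage clamp at E_K zeroes the Kv-only clamp current", {
  p <- male_params
  for (nm in c("P_Ca", "P_BKCa", "G_NaNSC", "G_KNSC", "G_Nab", "G_Kb",
               "G_Cab", "I_NaKmax", "P_NCX", "I_PMCAbar")) {
    p$channels[[nm]] <- 0
  }
  e_k <- nernst(1, p$conc$K_in, p$conc$K_out, p$const)
  st <- initial_state(p, e_k)
  cur <- derivatives(st, p, "voltage_clamp", V_cmd = e_k)$currents
  expect_equal(cur$I_ion, 0, tolerance = 1e-12)
})

test_that("true fixed point found by root-finding has vanishing derivatives", {
  for (p in list(male_params, female_params)) {
    v_star <- uniroot(function(V) {
      compute_currents(fixed_state(p, V), p)$I_ion
    }, c(-60, -15), tol = 1e-14)$root
    st <- fixed_state(p, v_star)
    d <- derivatives(st, p)$dstate
    norm <- abs(d) / (abs(st) + 1e-6)
    expect_lt(max(norm), 1e-6)
  }
})

test_that("Euler-Maruyama with zero noise is exactly forward Euler", {
  p <- male_params
  st <- initial_state(p)
  nc <- noise_config(0, 0, seed = 1, dt = 0.01)
  # reference: manual forward-Euler step via the exported reference stepper
  manual <- st + derivatives(st, p)$dstate * nc$dt
  for (g in c("dL", "dF", "X_Kv21act", "X_Kv15act", "X_ab", "ryr_state")) {
    manual[[g]] <- min(1, max(0, manual[[g]]))
  }
  stepped <- step_euler_maruyama(st, p, nc, randn = c(0, 0))
  expect_identical(stepped, manual[names(stepped)])
  # compiled trajectory with sigma = 0 is deterministic and seed-independent
  r1 <- simulate(p, 200, noise_config(0, 0, 1, 0.01), state = st,
                 discard_ms = 0, sample_every_ms = 1)
  r2 <- simulate(p, 200, noise_config(0, 0, 999, 0.01), state = st,
                 discard_ms = 0, sample_every_ms = 1)
  expect_identical(r1$state, r2$state)
})

test_that("same seed reproduces the stochastic trajectory exactly", {
  p <- male_params
  st <- initial_state(p)
  r1 <- simulate(p, 500, noise_config(0.35, 4e-6, 7, 0.01), state = st,
                 discard_ms = 0)
  r2 <- simulate(p, 500, noise_config(0.35, 4e-6, 7, 0.01), state = st,
                 discard_ms = 0)
  r3 <- simulate(p, 500, noise_config(0.35, 4e-6, 8, 0.01), state = st,
                 discard_ms = 0)
  expect_identical(r1$state, r2$state)
  expect_false(identical(r1$state, r3$state))
})

test_that("noise increments scale as sigma^2 dt with all currents disabled", {
  p <- silent_params
  st <- initial_state(p)
  sigma <- 0.5
  dt <- 0.01
  tr <- simulate(p, 10000 * dt, noise_config(sigma, 0, 3, dt), state = st,
                 discard_ms = 0, sample_every_ms = dt)
  dv <- diff(tr$state[, "V"])
  expect_equal(var(dv), sigma^2 * dt, tolerance = 0.05)
})

test_that("halving dt leaves the quiescent steady-state V unchanged to 0.1 mV", {
  # with the depolarizing NSC drive and Ca2+ entry removed the cell falls
  # to a quiescent hyperpolarized fixed point: cytosolic Ca2+ drops so low
  # that SERCA can no longer reload the SR to the spark threshold
  p <- scale_parameter(male_params, "G_NSC", 0)
  p$channels$P_Ca <- 0
  p$channels$G_Cab <- 0
  st <- initial_state(p, -60)
  v_end <- vapply(c(0.01, 0.005), function(dt) {
    tr <- simulate(p, 4000, noise_config(0, 0, 1, dt), state = st,
                   discard_ms = 0, sample_every_ms = 4)
    tr$state[nrow(tr$state), "V"]
  }, numeric(1))
  expect_lt(abs(diff(v_end)), 0.1)
  # quiescent: no transient hyperpolarizations in the final second
  tr <- simulate(p, 6000, noise_config(0, 0, 1, 0.01), state = st,
                 discard_ms = 5000)
  expect_lt(diff(range(tr$state[, "V"])), 0.5)
  expect_lt(tr$state[1, "V"], -55)
})

test_that("deterministic resting cell sustains a spark-STOC limit cycle", {
  tr <- simulate(male_params, 20000, noise_config(0, 0, 1, 0.01),
                 state = initial_state(male_params), discard_ms = 8000,
                 sample_every_ms = 1)
  V <- tr$state[, "V"]
  # sustained oscillation with transient hyperpolarizations of 10-15 mV
  amp <- median(V) - min(V)
  expect_gt(amp, 8)
  expect_lt(amp, 20)
  # junctional Ca2+ sparks reach the 10-20 uM band
  expect_gt(max(tr$state[, "Ca_Jun"]) * 1e3, 10)
  expect_lt(max(tr$state[, "Ca_Jun"]) * 1e3, 25)
  # deterministic period close to the noisy-run TH rate
  f_det <- th_frequency(tr)
  trn <- simulate(male_params, 20000, noise_config(0.35, 4e-6, 5, 0.01),
                  state = initial_state(male_params), discard_ms = 8000,
                  sample_every_ms = 1)
  f_noisy <- th_frequency(trn)
  expect_equal(f_det, f_noisy, tolerance = 0.35)
})

test_that("baseline potentials: male near -40 mV, female near -30 mV", {
  for (cfg in list(list(p = male_params, v = -40),
                   list(p = female_params, v = -30))) {
    tr <- simulate(cfg$p, 12000, noise_config(0.35, 4e-6, 11, 0.01),
                   state = initial_state(cfg$p), discard_ms = 6000,
                   sample_every_ms = 2)
    expect_equal(median(tr$state[, "V"]), cfg$v, tolerance = 0.08)
  }
})

test_that("mid-run drug events rescale parameters at the requested time", {
  p <- male_params
  tr <- simulate(p, 2000, noise_config(0, 0, 1, 0.01),
                 state = initial_state(p), discard_ms = 0,
                 sample_every_ms = 1,
                 events = list(list(t_ms = 1000, parameter = "G_Kv21",
                                    scale = 0)))
  i_kv21 <- tr$currents[, "I_Kv21"]
  expect_gt(mean(abs(i_kv21[tr$time < 990])), 0)
  expect_equal(max(abs(i_kv21[tr$time > 1010])), 0)
})

test_that("trace CSV writer emits metadata and one row per sample", {
  tr <- simulate(male_params, 100, noise_config(0, 0, 1, 0.01),
                 state = initial_state(male_params), discard_ms = 0,
                 sample_every_ms = 10)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# vsmsim trace: sex=male")
  df <- read.csv(f, comment.char = "#")
  expect_equal(nrow(df), length(tr$time))
  expect_true(all(c("time_ms", "V", "I_Kv21") %in% names(df)))
})
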