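# Experiment protocols and trace analysis.

test_that("drug block: identity at 0, silencing at 1, composition law", {
  p <- male_params
  p0 <- apply_drug(p, drug_block(fraction = 0))
  expect_identical(p0$channels$P_Ca, p$channels$P_Ca)
  p1 <- apply_drug(p, drug_block(fraction = 1))
  expect_identical(p1$channels$P_Ca, 0)
  f <- 0.4
  g <- 0.25
  pa <- apply_drug(apply_drug(p, drug_block(fraction = f)),
                   drug_block(fraction = g))
  pb <- apply_drug(p, drug_block(fraction = 1 - (1 - f) * (1 - g)))
  expect_equal(pa$channels$P_Ca, pb$channels$P_Ca, tolerance = 1e-12)
  expect_error(apply_drug(p, drug_block(target = "I_fake")), "unknown")
  expect_error(drug_block(fraction = 1.2), "\\[0, 1\\]")
})

test_that("kv_contributions: sums to 100, scale-invariant, errors at zero Kv", {
  kc <- kv_contributions(male_params, -40)
  expect_equal(sum(kc), 100)
  p2 <- scale_parameter(scale_parameter(male_params, "G_Kv21", 3),
                        "G_Kv15", 3)
  expect_equal(kv_contributions(p2, -40), kc, tolerance = 1e-10)
  p0 <- scale_parameter(scale_parameter(male_params, "G_Kv21", 0),
                        "G_Kv15", 0)
  expect_error(kv_contributions(p0, -40), "zero")
})

test_that("channel_count: anchors, zero, and half-away-from-zero ties", {
  # one male Kv2.1 channel open at -40 mV, three at -30 mV, 13 female at -30
  expect_equal(channel_count(0.8, 0.7)$count, 1L)
  expect_equal(channel_count(2.34, 0.7)$count, 3L)
  expect_equal(channel_count(9.2, 0.7)$count, 13L)
  expect_equal(channel_count(0, 0.7)$count, 0L)
  expect_equal(channel_count(1.75, 0.7)$count, 3L) # ratio exactly 2.5
  expect_equal(channel_count(1.75, 0.7)$ratio, 2.5)
  expect_error(channel_count(1, 0), "positive")
})

test_that("percent_change arithmetic", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 78), 22)
  expect_error(percent_change(0, 5), "zero baseline")
})

test_that("th_frequency: constructed fixture, flat trace, invariances", {
  # 14 square hyperpolarizations in 10 s -> 1.4 Hz
  dt <- 1
  t <- seq(0, 10000, dt)
  V <- rep(-40, length(t))
  starts <- seq(200, 9500, length.out = 14)
  for (s in starts) V[t >= s & t < s + 80] <- -50
  expect_equal(th_frequency(list(time = t, V = V)), 1.4, tolerance = 0.01)
  expect_equal(th_frequency(list(time = t, V = rep(-40, length(t)))), 0)
  # additive offset invariance
  expect_equal(th_frequency(list(time = t, V = V + 12.3)),
               th_frequency(list(time = t, V = V)))
  # doubling the sampling rate changes the count by at most one event
  t2 <- seq(0, 10000, 0.5)
  V2 <- rep(-40, length(t2))
  for (s in starts) V2[t2 >= s & t2 < s + 80] <- -50
  expect_lt(abs(th_frequency(list(time = t2, V = V2)) - 1.4), 0.11)
  expect_error(th_frequency(list(time = 1:100, V = rnorm(100))), "10 s")
})

test_that("single-exponential extraction recovers tau within 1%", {
  tt <- seq(0, 200, 0.5)
  y <- 5 + (0.2 - 5) * exp(-tt / 23)
  expect_equal(vsmsim:::.fit_single_exp(tt, y), 23, tolerance = 0.01)
})

test_that("iv_family: Kv2.1 peaks match anchors; female activates slower", {
  e_k <- nernst(1, model_conc$K_in, model_conc$K_out, model_const)
  prot <- clamp_protocol(steps = c(e_k, 0, 40), step_ms = 500, pre_ms = 300)
  iv_m <- iv_family(male_params, prot, "I_Kv21")
  iv_f <- iv_family(female_params, prot, "I_Kv21")
  # step to E_K gives no Kv current
  expect_equal(iv_m$peak[1], 0, tolerance = 1e-8)
  # +40 mV peaks reproduce the calibration anchors
  expect_equal(iv_m$peak[iv_m$V_step == 40][1], 68.8, tolerance = 0.01)
  expect_equal(iv_f$peak[iv_f$V_step == 40], 226.42, tolerance = 0.01)
  # female activation time constants exceed male at matched steps
  expect_gt(iv_f$tau_act_ms[iv_f$V_step == 0],
            iv_m$tau_act_ms[iv_m$V_step == 0])
  expect_gt(iv_f$tau_act_ms[iv_f$V_step == 40],
            iv_m$tau_act_ms[iv_m$V_step == 40])
  expect_error(iv_family(male_params, prot, "I_nope"), "unknown current")
})

test_that("parameter files: schema validation and scale_parameter guards", {
  f <- tempfile(fileext = ".json")
  write_parameters(male_params, f)
  back <- read_parameters(f)
  expect_equal(vsmsim:::.flatten_params(back),
               vsmsim:::.flatten_params(male_params), tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), bad, auto_unbox = TRUE)
  expect_error(read_parameters(bad), "schema")
  expect_error(scale_parameter(male_params, "G_whatever", 2), "unknown")
})
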