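test_that("protocol validation enforces its invariants", {
  expect_error(protocol_spec(data.frame(duration_s = -1, load_frac = 0.5)), "durations")
  expect_error(protocol_spec(data.frame(duration_s = 10, load_frac = 1.5)), "load_frac")
  expect_error(protocol_spec(data.frame(duration_s = 10, load_frac = 0.5), cadence_rpm = 0), "cadence")
  pr <- default_protocol()
  expect_s3_class(pr, "emg_protocol")
  expect_equal(pr$total_s, 1020)
  expect_equal(load_profile(pr, c(0, 400, 1019)), c(0.60, 0.925, 0.60))
})

test_that("lactate relaxes to baseline below threshold and VO2 reaches its setpoint", {
  pr <- protocol_spec(data.frame(duration_s = 1200, load_frac = 0.5))
  par <- metabolic_params(lactate_noise_sd = 0, vo2_noise_sd = 0)
  tr <- simulate_metabolics(pr, par, seed = 1)
  expect_equal(tail(tr$latent$lactate, 1), par$lactate_rest_mmol_l, tolerance = 1e-2)
  vset <- par$vo2_rest_l_min + par$vo2_slope_l_min * 0.5
  expect_equal(tail(tr$latent$vo2, 1), vset, tolerance = 1e-6)
})

test_that("three-phase protocol gives the rise-and-fall lactate shape, matching an ODE solver", {
  skip_if_not_installed("deSolve")
  par <- metabolic_params(lactate_noise_sd = 0, vo2_noise_sd = 0)
  pr <- default_protocol()
  tr <- simulate_metabolics(pr, par, seed = 1)

  edges <- cumsum(pr$phases$duration_s)
  l <- tr$latent$lactate
  t <- tr$latent$time_s
  # maximal near the end of phase 2, declining through phase 3
  expect_equal(t[which.max(l)], edges[2], tolerance = 0.02)
  expect_lt(tail(l, 1), max(l))
  expect_gt(max(l), 5) # heavy phase drives real accumulation

  # independent integrator oracle
  rhs <- function(tt, state, p) {
    load <- load_profile(pr, min(tt, pr$total_s - 1e-9))
    dl <- p$lactate_gain * max(0, load - p$lactate_threshold) -
      p$lactate_clearance * (state[1] - p$lactate_rest_mmol_l)
    dv <- (p$vo2_rest_l_min + p$vo2_slope_l_min * load - state[2]) / p$vo2_tau_s
    list(c(dl, dv))
  }
  sol <- deSolve::ode(
    y = c(par$lactate_rest_mmol_l, par$vo2_rest_l_min),
    times = t, func = rhs, parms = par, method = "rk4"
  )
  expect_equal(l, unname(sol[, 2]), tolerance = 1e-3)
  expect_equal(tr$latent$vo2, unname(sol[, 3]), tolerance = 1e-3)
})

test_that("zero clearance above threshold gives strictly increasing lactate", {
  pr <- protocol_spec(data.frame(duration_s = 300, load_frac = 1.0))
  par <- metabolic_params(
    lactate_clearance = 0,
    lactate_noise_sd = 0, vo2_noise_sd = 0
  )
  tr <- simulate_metabolics(pr, par, seed = 1)
  expect_true(all(diff(tr$latent$lactate) > 0))
})

test_that("metabolic curves are non-negative and sampled on the measurement grids", {
  tr <- simulate_metabolics(default_protocol(), seed = 42)
  expect_true(all(tr$lactate$value >= 0))
  expect_true(all(tr$vo2$value >= 0))
  expect_equal(diff(tr$lactate$time_s), rep(60, nrow(tr$lactate) - 1))
  expect_equal(diff(tr$vo2$time_s), rep(10, nrow(tr$vo2) - 1))
})

test_that("metabolic parameter validation rejects non-positive rates", {
  expect_error(metabolic_params(lactate_gain = 0), "lactate_gain")
  expect_error(metabolic_params(vo2_tau_s = -1), "time constants")
})

test_that("zero noise yields silence between exactly one burst per cycle", {
  pr <- protocol_spec(data.frame(duration_s = 2, load_frac = 0.6)) # 3 cycles
  sim <- simulate_emg(pr, NULL, "VL_right",
    params = emg_params(noise_sd_mv = 0, jitter_s = 0), seed = 1
  )
  expect_equal(nrow(sim$onsets), 3)
  s <- sim$emg$VL_right
  burst_len <- round(1 / 3 * 60 / 90 * 1000)
  inside <- unlist(lapply(sim$onsets$onset_sample, function(o) o:(o + burst_len - 1)))
  expect_true(all(s[-inside] == 0))
  expect_true(all(tapply(
    abs(s[inside]) > 0,
    rep(seq_len(3), each = burst_len), any
  )))
})

test_that("identical seeds give bit-identical recordings; different seeds differ", {
  pr <- protocol_spec(data.frame(duration_s = 3, load_frac = 0.6))
  a <- simulate_emg(pr, NULL, c("VL_right", "BF_left"), seed = 9)
  b <- simulate_emg(pr, NULL, c("VL_right", "BF_left"), seed = 9)
  expect_identical(a$emg, b$emg)
  expect_identical(a$onsets, b$onsets)
  d <- simulate_emg(pr, NULL, c("VL_right", "BF_left"), seed = 10)
  expect_false(identical(a$emg, d$emg))
})

test_that("burst count and inter-onset interval follow the cadence grid", {
  for (cadence in c(90, 100)) {
    pr <- protocol_spec(
      data.frame(duration_s = c(20, 15), load_frac = c(0.6, 0.9)),
      cadence_rpm = cadence
    )
    sim <- simulate_emg(pr, NULL, "RF_left",
      params = emg_params(jitter_s = 0), seed = 3
    )
    expected <- sum(floor(pr$phases$duration_s * cadence / 60))
    expect_lte(abs(nrow(sim$onsets) - expected), 2) # +-1 per phase
    gaps <- diff(sim$onsets$onset_time_s)
    expect_lt(abs(mean(gaps) - 60 / cadence), 0.02 * 60 / cadence)
    expect_true(all(diff(sim$onsets$onset_sample) > 0))
  }
})

test_that("doubling the amplitude scale exactly doubles per-burst RMS", {
  pr <- protocol_spec(data.frame(duration_s = 4, load_frac = 0.6))
  base <- emg_params(noise_sd_mv = 0, jitter_s = 0, amp_base_mv = 0.2)
  doubled <- emg_params(noise_sd_mv = 0, jitter_s = 0, amp_base_mv = 0.4)
  s1 <- simulate_emg(pr, NULL, "VL_right", params = base, seed = 4)
  s2 <- simulate_emg(pr, NULL, "VL_right", params = doubled, seed = 4)
  burst_len <- round(1 / 3 * 60 / 90 * 1000)
  rms <- function(sim) sapply(sim$onsets$onset_sample, function(o) {
    sqrt(mean(sim$emg$VL_right[o:(o + burst_len - 1)]^2))
  })
  expect_equal(rms(s2), 2 * rms(s1), tolerance = 1e-12)
})

test_that("generator rejects impossible burst geometry and bad labels", {
  pr <- protocol_spec(data.frame(duration_s = 4, load_frac = 0.6))
  expect_error(emg_params(burst_frac = 1.2), "burst_frac")
  expect_error(simulate_emg(pr, NULL, "XX_up", seed = 1), "invalid channel label")
  expect_error(emg_params(jitter_s = 0.05), "jitter_s")
})
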