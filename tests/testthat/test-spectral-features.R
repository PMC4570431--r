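test_that("band plan reproduces the printed six-bin geometry", {
  plan <- band_plan(256, 1000)
  expect_equal(nrow(plan), 19)
  widths <- plan$f_hi_hz - plan$f_lo_hz
  expect_equal(widths, rep(6 * 1000 / 256, 19)) # 23.4375 Hz
  overlaps <- plan$f_hi_hz[-19] - plan$f_lo_hz[-1]
  expect_equal(overlaps, rep(3 * 1000 / 256, 18)) # 11.71875 Hz
  expect_equal(plan$f_lo_hz[1], 23.4375)
  expect_equal(plan$f_hi_hz[1], 46.875)
  expect_equal(plan$f_lo_hz[19], 234.375)
  expect_equal(plan$f_hi_hz[19], 257.8125)
  expect_equal(plan$name[1], "p23_47")
  expect_equal(plan$name[19], "p234_258")
  expect_error(band_plan(64, 1000), "band plan")
})

test_that("power distribution has unit area, is scale-invariant and localises a tone", {
  set.seed(2)
  seg <- rnorm(256)
  d <- power_distribution(seg, fs = 1000)
  df <- d$freq_hz[2] - d$freq_hz[1]
  expect_equal(sum(d$density) * df, 1, tolerance = 1e-9)
  expect_equal(df, 3.90625)
  expect_true(all(d$density >= 0))

  d10 <- power_distribution(10 * seg, fs = 1000)
  expect_equal(d10$density, d$density, tolerance = 1e-12)

  # 125 Hz sits exactly on bin 32; the Hamming window keeps >= 95% of the
  # mass within +-2 bins
  tone <- sin(2 * pi * 125 * (0:255) / 1000)
  dt <- power_distribution(tone, fs = 1000)
  near <- abs(dt$freq_hz - 125) <= 2 * df
  expect_gte(sum(dt$density[near]) / sum(dt$density), 0.95)

  expect_warning(power_distribution(rep(0, 256)), "all-zero")
})

test_that("time-domain features follow their definitions", {
  td <- time_domain_features(c(3, -4))
  expect_equal(unname(td["RMS"]), sqrt(12.5))
  expect_equal(unname(td["dRMS"]), 7)
  expect_equal(unname(td["IF"]), 0.5)

  # phase offset keeps samples off exact zeros (which are skipped, not
  # counted); a 256-sample window spans 31.875 periods, so the strict
  # discrete count may miss the boundary crossing: 2 * 125 * 0.256 = 64
  # crossings, observed as 63-64
  tone <- sin(2 * pi * 125 * (0:255) / 1000 + 0.3)
  expect_lte(abs(unname(time_domain_features(tone)["IF"]) - 32), 0.5)

  const <- time_domain_features(rep(2, 100))
  expect_equal(unname(const["dRMS"]), 0)
  expect_equal(unname(const["IF"]), 0)
})

test_that("distribution moments match direct weighted sums", {
  f <- seq(0, 500, by = 500 / 128)
  dens <- rep(0, 129)
  # symmetric two-bin mass at 100 and 200 Hz (not bin centres; use nearest)
  i100 <- which.min(abs(f - 100))
  i200 <- which.min(abs(f - 200))
  dens[c(i100, i200)] <- 1
  d <- tibble::tibble(freq_hz = f, power = dens, density = dens / (sum(dens) * (f[2] - f[1])))
  m <- distribution_moments(d)
  expect_equal(unname(m["MnF"]), (f[i100] + f[i200]) / 2)
  expect_equal(unname(m["Skew"]), 0, tolerance = 1e-9)

  one <- dens * 0
  one[i100] <- 1
  d1 <- tibble::tibble(freq_hz = f, power = one, density = one / (sum(one) * (f[2] - f[1])))
  m1 <- distribution_moments(d1)
  expect_equal(unname(m1["ModF"]), f[i100])
  expect_equal(unname(m1["StD"]), 0)
  expect_equal(unname(m1["Kurt"]), 0) # degenerate convention

  # 4-bin density against the brute-force oracle
  f4 <- c(50, 100, 150, 200)
  w4 <- c(0.1, 0.4, 0.3, 0.2)
  d4 <- tibble::tibble(freq_hz = f4, power = w4, density = w4 / (sum(w4) * 50))
  m4 <- distribution_moments(d4)
  o <- oracle_moments(f4, w4)
  expect_equal(unname(m4["MnF"]), o$mean, tolerance = 1e-12)
  expect_equal(unname(m4["StD"]), o$sd, tolerance = 1e-12)
  expect_equal(unname(m4["Skew"]), o$skew, tolerance = 1e-12)
  expect_equal(unname(m4["Kurt"]), o$kurt, tolerance = 1e-12)
})

test_that("percentiles invert the cumulative distribution", {
  f <- seq(0, 500, by = 500 / 128)
  df <- f[2] - f[1]
  flat <- rep(1, 129)
  d <- tibble::tibble(freq_hz = f, power = flat, density = flat / (sum(flat) * df))
  q <- distribution_percentiles(d)
  expect_true(all(abs(q - 500 * seq(0.1, 0.9, 0.1)) <= df / 2 + 1e-9))
  expect_true(all(diff(q) >= 0))

  spike <- rep(0, 129)
  i100 <- which.min(abs(f - 100))
  spike[i100] <- 1
  ds <- tibble::tibble(freq_hz = f, power = spike, density = spike / (sum(spike) * df))
  qs <- distribution_percentiles(ds)
  expect_true(all(abs(qs - f[i100]) <= df / 2 + 1e-9))

  # arbitrary 8-bin density against the cumulative-crossing oracle
  set.seed(4)
  f8 <- seq(0, 350, by = 50)
  w8 <- runif(8)
  d8 <- tibble::tibble(freq_hz = f8, power = w8, density = w8 / (sum(w8) * 50))
  q8 <- distribution_percentiles(d8)
  for (i in seq_along(q8)) {
    expect_equal(unname(q8[i]), oracle_percentile(f8, w8, i / 10), tolerance = 1e-12)
  }
})

test_that("band powers are fractions of total power with the fixed bin plan", {
  f <- seq(0, 500, by = 500 / 128)
  flat <- rep(1, 129)
  d <- tibble::tibble(freq_hz = f, power = flat, density = flat / (sum(flat) * (f[2] - f[1])))
  bp <- band_powers(d, fs = 1000)
  expect_equal(length(bp), 19)
  expect_equal(unname(bp), rep(6 / 129, 19), tolerance = 1e-12)

  tone <- sin(2 * pi * 30 * (0:255) / 1000)
  dt <- power_distribution(tone, fs = 1000)
  bpt <- band_powers(dt, fs = 1000)
  expect_equal(names(which.max(bpt)), "p23_47")
  expect_true(all(bp >= 0 & bp <= 1))
})

test_that("feature assembly yields 36 named variables per segment in order", {
  sim <- quick_sim(duration_s = 10, seed = 41)
  segs <- quick_segment(sim)
  feats <- assemble_features(segs)
  expect_equal(nrow(feats), nrow(segs))
  expect_equal(setdiff(names(feats), c("channel", "time_s")), feature_names())
  expect_equal(length(feature_names()), 36)
  expect_false(anyNA(feats))

  # percentile monotonicity for every segment
  qcols <- as.matrix(feats[paste0("q", seq(10, 90, 10))])
  expect_true(all(t(apply(qcols, 1, diff)) >= 0))
  # frequencies bounded by Nyquist, band powers are fractions
  expect_true(all(feats$MnF >= 0 & feats$MnF <= 500))
  expect_true(all(feats$ModF >= 0 & feats$ModF <= 500))
  pcols <- as.matrix(feats[band_plan()$name])
  expect_true(all(pcols >= 0 & pcols <= 1))

  # column 13 of the 36 (q50, the median power frequency) recomputed
  # independently from the raw segments
  for (i in c(1, 5, 9)) {
    d <- power_distribution(segs$segment[[i]], fs = 1000)
    expect_equal(
      feats$q50[i],
      oracle_percentile(d$freq_hz, d$density, 0.5),
      tolerance = 1e-9
    )
  }
})

test_that("frequency features are amplitude-invariant; RMS and dRMS scale linearly", {
  sim <- quick_sim(duration_s = 8, seed = 43)
  segs <- quick_segment(sim)
  feats <- assemble_features(segs)
  scaled <- segs
  scaled$segment <- lapply(segs$segment, function(s) 4 * s)
  feats4 <- assemble_features(scaled)
  expect_equal(feats4$RMS, 4 * feats$RMS, tolerance = 1e-12)
  expect_equal(feats4$dRMS, 4 * feats$dRMS, tolerance = 1e-12)
  freq_cols <- setdiff(feature_names(), c("RMS", "dRMS"))
  expect_equal(feats4[freq_cols], feats[freq_cols], tolerance = 1e-9)
})

test_that("median smoothing matches the naive oracle and handles edges", {
  x <- rep(5, 30)
  sm <- median_smooth(tibble::tibble(time_s = 1:30, RMS = x), window = 11, cols = "RMS")
  expect_equal(sm$RMS, x)

  spike <- x
  spike[15] <- 100
  sm2 <- median_smooth(tibble::tibble(time_s = 1:30, RMS = spike), window = 11, cols = "RMS")
  expect_equal(sm2$RMS, x)

  set.seed(6)
  y <- rnorm(57)
  sm3 <- median_smooth(tibble::tibble(time_s = 1:57, RMS = y), window = 11, cols = "RMS")
  expect_equal(sm3$RMS, oracle_running_median(y, 11))
  expect_error(
    median_smooth(tibble::tibble(time_s = 1:10, RMS = rnorm(10)), window = 10),
    "odd"
  )
})

test_that("a planted spectral tail drift moves the upper percentiles upward", {
  pr <- protocol_spec(data.frame(
    duration_s = c(30, 30),
    load_frac = c(0.6, 0.925)
  ))
  truth <- simulate_metabolics(pr, seed = 5)
  # zero baseline noise isolates the planted spectral drift (with noise the
  # amplitude-dependent SNR itself shifts the percentiles)
  sim <- simulate_emg(pr, truth, "VL_right",
    params = emg_params(tail_mass = 0.1, tail_drift = 0.6, jitter_s = 0, noise_sd_mv = 0),
    seed = 5
  )
  segs <- quick_segment(sim)
  feats <- median_smooth(assemble_features(segs))
  ex <- stats::approx(truth$latent$time_s, truth$latent$exertion, feats$time_s)$y
  rs_drift <- suppressWarnings(spearman_cor(ex, feats$q90))
  expect_gt(rs_drift, 0.5)
  # and without drift there is no such trend
  sim0 <- simulate_emg(pr, truth, "VL_right",
    params = emg_params(tail_mass = 0.1, tail_drift = 0, jitter_s = 0, noise_sd_mv = 0),
    seed = 5
  )
  feats0 <- median_smooth(assemble_features(quick_segment(sim0)))
  ex0 <- stats::approx(truth$latent$time_s, truth$latent$exertion, feats0$time_s)$y
  rs_flat <- suppressWarnings(spearman_cor(ex0, feats0$q90))
  expect_lt(abs(rs_flat), 0.4)
  expect_gt(rs_drift, rs_flat + 0.4)
})
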