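# Independent oracles and small fixture builders used across the suite.
# Each oracle is coded from first principles, separately from the package
# implementation it checks.

# Cubic Hermite interpolation via explicit basis polynomials h00..h11 with
# Catmull-Rom (centred finite difference) tangents.
oracle_hermite <- function(t, v, q) {
  n <- length(t)
  m <- numeric(n)
  m[1] <- (v[2] - v[1]) / (t[2] - t[1])
  m[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    for (i in 2:(n - 1)) m[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  sapply(q, function(x) {
    k <- max(which(t <= x))
    if (k == n) k <- n - 1
    h <- t[k + 1] - t[k]
    u <- (x - t[k]) / h
    (2 * u^3 - 3 * u^2 + 1) * v[k] +
      (u^3 - 2 * u^2 + u) * h * m[k] +
      (-2 * u^3 + 3 * u^2) * v[k + 1] +
      (u^3 - u^2) * h * m[k + 1]
  })
}

# Naive running median, sort-and-pick, shrinking centred windows.
oracle_running_median <- function(x, w) {
  h <- (w - 1) %/% 2
  sapply(seq_along(x), function(i) {
    win <- sort(x[max(1, i - h):min(length(x), i + h)])
    m <- length(win)
    if (m %% 2 == 1) win[(m + 1) / 2] else (win[m / 2] + win[m / 2 + 1]) / 2
  })
}

# Spearman closed form for tie-free data: 1 - 6 sum(d^2) / (n (n^2 - 1)).
oracle_spearman_closed_form <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# Ridge solution by a different route: augmented least squares on
# rbind(X, sqrt(lambda) I) with zero-extended response.
oracle_ridge_augmented <- function(x, y, lambda) {
  p <- ncol(x)
  xa <- rbind(x, sqrt(lambda) * diag(p))
  ya <- c(y, rep(0, p))
  qr.solve(xa, ya)
}

# Weighted moments of a discrete distribution by direct sums.
oracle_moments <- function(f, w) {
  w <- w / sum(w)
  mu <- sum(f * w)
  m2 <- sum((f - mu)^2 * w)
  list(
    mean = mu, sd = sqrt(m2),
    skew = sum((f - mu)^3 * w) / m2^1.5,
    kurt = sum((f - mu)^4 * w) / m2^2 - 3
  )
}

# Percentile by brute-force cumulative crossing with uniform-in-bin mass.
oracle_percentile <- function(f, mass, p) {
  df <- f[2] - f[1]
  mass <- mass / sum(mass)
  cum <- cumsum(mass)
  k <- which(cum >= p - 1e-15)[1]
  prev <- if (k == 1) 0 else cum[k - 1]
  left <- max(f[k] - df / 2, 0)
  right <- min(f[k] + df / 2, max(f))
  left + (p - prev) / mass[k] * (right - left)
}

# Short synthetic recording for segmentation/feature tests.
quick_sim <- function(duration_s = 20, channels = "VL_right", seed = 1,
                      jitter_s = 0.005, noise_sd_mv = 0.01, ...) {
  pr <- protocol_spec(
    data.frame(duration_s = duration_s, load_frac = 0.6),
    cadence_rpm = 90
  )
  simulate_emg(pr, NULL, channels,
    params = emg_params(jitter_s = jitter_s, noise_sd_mv = noise_sd_mv, ...),
    seed = seed
  )
}

# Filter + segment in one go, silencing stage chatter.
quick_segment <- function(sim, ...) {
  suppressMessages(suppressWarnings(
    segment_emg(bandpass_emg(sim$emg), cadence_rpm = 90, ...)
  ))
}
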