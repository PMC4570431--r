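#' Frequency-band plan for relative band powers
#'
#' The 19 overlapping bands are defined directly on DFT bins: each band is
#' 6 bins wide and consecutive bands start 3 bins apart, beginning at bin 6.
#' With the default 256-sample segment at 1000 Hz the bin width is
#' 3.90625 Hz, so the bands are 23.44 Hz wide with 11.72 Hz overlap, the
#' first covering 23.44-46.88 Hz and the last 234.4-257.8 Hz.
#'
#' @param n Segment length in samples (default 256).
#' @param fs Sampling rate in Hz (default 1000).
#' @return Tibble with one row per band: `band` (1-19), `bin_lo`/`bin_hi`
#'   (0-based DFT bin indices, inclusive), `f_lo_hz`/`f_hi_hz` (band edges
#'   in Hz) and `name` (column name, e.g. `"p23_47"`).
#' @export
#' @examples
#' band_plan()
band_plan <- function(n = 256, fs = 1000) {
  df <- fs / n
  n_onesided <- n %/% 2 + 1
  k <- 0:18
  bin_lo <- 6 + 3 * k
  bin_hi <- bin_lo + 5
  if (max(bin_hi) >= n_onesided) {
    abort("segment length / sampling rate incompatible with the fixed 19-band plan; supply an explicit band table")
  }
  f_lo <- bin_lo * df
  f_hi <- (bin_hi + 1) * df
  tibble::tibble(
    band = k + 1L,
    bin_lo = bin_lo, bin_hi = bin_hi,
    f_lo_hz = f_lo, f_hi_hz = f_hi,
    name = paste0("p", round(f_lo), "_", round(f_hi))
  )
}

#' Names of the 36 segment variables, in canonical order
#'
#' Time-domain RMS, dRMS and IF (1-3); power-distribution moments ModF,
#' MnF, StD, Skew, Kurt (4-8); every tenth percentile q10-q90 (9-17, with
#' q50 the median power frequency, MPF); and 19 relative band powers
#' (18-36).
#'
#' @inheritParams band_plan
#' @return Character vector of length 36.
#' @export
feature_names <- function(n = 256, fs = 1000) {
  c(
    "RMS", "dRMS", "IF", "ModF", "MnF", "StD", "Skew", "Kurt",
    paste0("q", seq(10, 90, by = 10)),
    band_plan(n, fs)$name
  )
}

#' Normalised power distribution of a segment
#'
#' Applies a Hamming window (0.54 - 0.46 cos), takes the squared magnitude
#' of the one-sided DFT, and normalises the resulting power spectrum to
#' enclose unit area over 0..Nyquist (Riemann sum: `sum(density * df) = 1`).
#'
#' @param segment Numeric vector of `n` samples.
#' @param fs Sampling rate in Hz.
#' @return Tibble with `freq_hz` (bin centres, 0..Nyquist), `power` (raw
#'   windowed power) and `density` (normalised, unit area).  An all-zero
#'   segment yields zero density with a warning.
#' @export
power_distribution <- function(segment, fs = 1000) {
  n <- length(segment)
  if (n < 4) abort("segment too short")
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  p_full <- Mod(fft(segment * w))^2
  m <- n %/% 2 + 1
  p <- p_full[seq_len(m)]
  df <- fs / n
  total <- sum(p) * df
  if (total == 0) {
    warn("all-zero segment: power distribution is degenerate (zero density)")
    dens <- rep(0, m)
  } else {
    dens <- p / total
  }
  tibble::tibble(freq_hz = (seq_len(m) - 1) * df, power = p, density = dens)
}

#' Time-domain segment features: RMS, dRMS and IF
#'
#' RMS of the segment, RMS of its backward difference, and the
#' zero-crossing count divided by two ("instantaneous frequency"; a count
#' per segment, not rescaled to Hz).  Crossings are strict sign changes;
#' exact zeros are skipped.
#'
#' @param segment Numeric vector, length >= 2.
#' @return Named numeric vector `c(RMS, dRMS, IF)`.
#' @export
time_domain_features <- function(segment) {
  if (length(segment) < 2) abort("segment must have at least 2 samples")
  delta <- diff(segment)
  sgn <- sign(segment)
  sgn <- sgn[sgn != 0]
  crossings <- if (length(sgn) >= 2) sum(diff(sgn) != 0) else 0L
  c(
    RMS = sqrt(mean(segment^2)),
    dRMS = sqrt(mean(delta^2)),
    IF = crossings / 2
  )
}

#' Moments of the power distribution
#'
#' Mode, mean, standard deviation, skewness and excess kurtosis of
#' frequency under the normalised power distribution.  The DC bin is
#' included in the distribution but excluded from the mode (the high-pass
#' stage makes it ~0 anyway; excluding it avoids a spurious 0 Hz mode).
#' Degenerate distributions (all mass in one bin, or zero) report
#' `StD = 0` and `Skew = Kurt = 0` by convention.
#'
#' @param dist Tibble from [power_distribution()].
#' @return Named numeric vector `c(ModF, MnF, StD, Skew, Kurt)`.
#' @export
distribution_moments <- function(dist) {
  f <- dist$freq_hz
  df <- f[2] - f[1]
  wts <- dist$density * df
  tot <- sum(wts)
  if (tot <= 0) {
    return(c(ModF = 0, MnF = 0, StD = 0, Skew = 0, Kurt = 0))
  }
  wts <- wts / tot
  nz <- which(f > 0)
  modf <- f[nz][which.max(dist$density[nz])]
  mu <- sum(f * wts)
  m2 <- sum((f - mu)^2 * wts)
  if (m2 <= 0) {
    return(c(ModF = modf, MnF = mu, StD = 0, Skew = 0, Kurt = 0))
  }
  m3 <- sum((f - mu)^3 * wts)
  m4 <- sum((f - mu)^4 * wts)
  c(
    ModF = modf, MnF = mu, StD = sqrt(m2),
    Skew = m3 / m2^1.5, Kurt = m4 / m2^2 - 3
  )
}

#' Percentiles of the power distribution
#'
#' Inverse of the cumulative power distribution at p = 0.1 .. 0.9.  Each
#' DFT bin's mass is treated as uniform over the bin (centre +- half a bin
#' width, clipped to 0..Nyquist), and the crossing bin is resolved by
#' linear interpolation.  `q50` is the median power frequency (MPF).
#'
#' @param dist Tibble from [power_distribution()].
#' @param probs Probabilities (default `seq(0.1, 0.9, 0.1)`).
#' @return Named numeric vector `q10` .. `q90` (Hz).
#' @export
distribution_percentiles <- function(dist, probs = seq(0.1, 0.9, by = 0.1)) {
  f <- dist$freq_hz
  df <- f[2] - f[1]
  mass <- dist$density * df
  tot <- sum(mass)
  out <- stats::setNames(rep(0, length(probs)), paste0("q", round(100 * probs)))
  if (tot <= 0) {
    return(out)
  }
  mass <- mass / tot
  cum <- cumsum(mass)
  left <- pmax(f - df / 2, 0)
  right <- pmin(f + df / 2, max(f))
  for (i in seq_along(probs)) {
    p <- probs[i]
    k <- which(cum >= p - 1e-15)[1]
    prev <- if (k == 1) 0 else cum[k - 1]
    frac <- if (mass[k] > 0) (p - prev) / mass[k] else 0
    out[i] <- left[k] + frac * (right[k] - left[k])
  }
  out
}

#' Relative power in the 19 overlapping frequency bands
#'
#' Sums the raw one-sided power spectrum over each band of the fixed
#' six-bin plan (see [band_plan()]) and divides by total one-sided power,
#' giving 19 fractions in `[0, 1]`.
#'
#' @param dist Tibble from [power_distribution()].
#' @param fs Sampling rate in Hz (with the segment length, fixes the bin
#'   plan; non-matching geometries are an error).
#' @return Named numeric vector of 19 band-power fractions.
#' @export
band_powers <- function(dist, fs = 1000) {
  m <- nrow(dist)
  n <- 2 * (m - 1)
  plan <- band_plan(n, fs)
  df_expected <- fs / n
  if (abs((dist$freq_hz[2] - dist$freq_hz[1]) - df_expected) > 1e-9) {
    abort("power spectrum bin width does not match the fixed band plan")
  }
  tot <- sum(dist$power)
  vals <- vapply(seq_len(nrow(plan)), function(i) {
    idx <- (plan$bin_lo[i]:plan$bin_hi[i]) + 1L # 0-based bins -> R index
    if (tot > 0) sum(dist$power[idx]) / tot else 0
  }, numeric(1))
  stats::setNames(vals, plan$name)
}

# All 36 variables for one segment, as a named numeric vector.
segment_features <- function(segment, fs = 1000) {
  dist <- withCallingHandlers(
    power_distribution(segment, fs),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (sum(dist$power) == 0) {
    warn("all-zero segment: features set to 0")
    return(stats::setNames(
      rep(0, 36), feature_names(length(segment), fs)
    ))
  }
  c(
    time_domain_features(segment),
    distribution_moments(dist),
    distribution_percentiles(dist),
    band_powers(dist, fs)
  )
}

#' Compute the 36-variable feature matrix for a segment set
#'
#' One row per segment, in onset order, with the 36 variables in canonical
#' order (see [feature_names()]) plus the segment timestamp and channel.
#'
#' @param segments Tibble from [segment_emg()] (columns `channel`,
#'   `onset_sample`, `onset_time_s`, `segment`).
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `channel`, `time_s`, then the 36 variables.
#' @export
#' @examples
#' pr <- protocol_spec(data.frame(duration_s = 5, load_frac = 0.6))
#' sim <- simulate_emg(pr, NULL, "VL_right", seed = 3)
#' feats <- assemble_features(segment_emg(bandpass_emg(sim$emg)))
#' dim(feats)
assemble_features <- function(segments, fs = 1000) {
  if (nrow(segments) == 0) abort("empty segment set")
  rows <- purrr::map(segments$segment, segment_features, fs = fs)
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(
      channel = segments$channel,
      time_s = segments$onset_time_s
    ),
    tibble::as_tibble(mat)
  ) |>
    dplyr::arrange(.data$channel, .data$time_s)
}

# Running median with centred window and shrinking edges.
running_median <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Median-smooth a feature matrix over time
#'
#' Applies an 11-point (by default) centred running median to every feature
#' column, per channel, suppressing segment-to-segment variability so
#' slower physiological trends are not masked by noise.  Edge positions use
#' the median of the available (shrunken) window, so the output has the
#' same number of rows as the input.
#'
#' @param features Tibble from [assemble_features()].
#' @param window Odd window length in data points (default 11, roughly
#'   9-10 s of pedalling).
#' @param cols Columns to smooth (default: all 36 feature columns present).
#' @return Tibble of the same shape with smoothed feature columns.
#' @export
median_smooth <- function(features, window = 11, cols = NULL) {
  if (window %% 2 == 0) abort("window must be odd")
  if (is.null(cols)) {
    cols <- intersect(feature_names(), names(features))
    if (length(cols) == 0) cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))],
      c("time_s", "onset_sample")
    )
  }
  grouped <- "channel" %in% names(features)
  smooth_block <- function(df) {
    df <- dplyr::arrange(df, .data$time_s)
    for (cl in cols) df[[cl]] <- running_median(df[[cl]], window)
    df
  }
  if (grouped) {
    features |>
      dplyr::group_by(.data$channel) |>
      dplyr::group_modify(~ smooth_block(.x)) |>
      dplyr::ungroup()
  } else {
    smooth_block(features)
  }
}
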