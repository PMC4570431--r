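#' EMG generator parameters
#'
#' Controls the synthetic sEMG produced by [simulate_emg()].  Each pedal
#' revolution contributes one activity burst per channel: band-limited
#' coloured Gaussian noise (20-400 Hz) under a smooth Hann activation
#' envelope, so the within-cycle activity pattern repeats from cycle to
#' cycle (cyclic stationarity).  Burst amplitude and the high-frequency
#' tail mass of the burst spectrum can be driven by the latent exertion
#' trajectory from [simulate_metabolics()].
#'
#' @param burst_frac Burst duration as a fraction of the pedal cycle
#'   (default 1/3; must be < 1).
#' @param amp_base_mv Base burst amplitude scale (mV).  Per-burst RMS is
#'   `amp_base_mv * (0.25 + amp_gain * exertion(t))`, so `amp_base_mv` is an
#'   exact linear gain.
#' @param amp_gain Sensitivity of burst RMS to exertion (dimensionless).
#' @param band_lo_hz,band_hi_hz Burst spectral support (Hz).
#' @param band_split_hz Boundary between the "body" and the "tail" of the
#'   burst spectrum (Hz).
#' @param tail_mass Fraction of burst power above `band_split_hz` at zero
#'   exertion drift, in (0, 1).
#' @param tail_drift Added tail mass per unit exertion; planting a positive
#'   drift moves upper power-distribution percentiles (q0.8, q0.9) upward
#'   with exertion.
#' @param jitter_s Burst onsets are jittered uniformly in `[-jitter_s,
#'   jitter_s]` around the cadence grid (default 0.005 s, at most 0.010 s).
#' @param noise_sd_mv Standard deviation of the white inter-burst baseline
#'   noise (mV); 0 gives silence between bursts.
#'
#' @return A named list of class `emg_params`.
#' @export
emg_params <- function(burst_frac = 1 / 3,
                       amp_base_mv = 0.2,
                       amp_gain = 1.0,
                       band_lo_hz = 20,
                       band_hi_hz = 400,
                       band_split_hz = 180,
                       tail_mass = 0.25,
                       tail_drift = 0,
                       jitter_s = 0.005,
                       noise_sd_mv = 0.01) {
  if (burst_frac <= 0 || burst_frac >= 1) abort("burst_frac must be in (0, 1)")
  if (jitter_s < 0 || jitter_s > 0.010) abort("jitter_s must be in [0, 0.010]")
  if (tail_mass <= 0 || tail_mass >= 1) abort("tail_mass must be in (0, 1)")
  if (!(band_lo_hz < band_split_hz && band_split_hz < band_hi_hz)) {
    abort("need band_lo_hz < band_split_hz < band_hi_hz")
  }
  if (noise_sd_mv < 0) abort("noise_sd_mv must be >= 0")
  structure(
    list(
      burst_frac = burst_frac, amp_base_mv = amp_base_mv, amp_gain = amp_gain,
      band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
      band_split_hz = band_split_hz, tail_mass = tail_mass,
      tail_drift = tail_drift, jitter_s = jitter_s, noise_sd_mv = noise_sd_mv
    ),
    class = "emg_params"
  )
}

# Within-cycle activation offsets (fractions of the pedal cycle) for the four
# muscles; the left leg works half a cycle out of phase with the right.
.muscle_phase <- c(VL = 0.30, RF = 0.38, ST = 0.85, BF = 0.92)

# One burst of band-limited coloured noise with a Hann envelope and exact
# target RMS.  tail_w = fraction of spectral weight above band_split_hz.
make_burst <- function(n, fs, params, tail_w, target_rms) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # map to [0, fs/2]
  lo <- freqs >= params$band_lo_hz & freqs <= params$band_split_hz
  hi <- freqs > params$band_split_hz & freqs <= params$band_hi_hz
  w <- numeric(n)
  if (any(lo)) w[lo] <- sqrt((1 - tail_w) / sum(lo))
  if (any(hi)) w[hi] <- sqrt(tail_w / sum(hi))
  y <- Re(fft(X * w, inverse = TRUE)) / n
  # Tukey (20% taper) activation envelope: near-immediate energy onset, so
  # the ground-truth onset marks where burst energy actually starts, with
  # smooth rise/fall edges keeping the within-cycle pattern consistent
  r <- 0.2
  u <- (seq_len(n) - 1) / (n - 1)
  env <- rep(1, n)
  lo <- u < r / 2
  hi <- u > 1 - r / 2
  env[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / r - 1)))
  env[hi] <- 0.5 * (1 + cos(pi * (2 * (u[hi] - 1 + r / 2) / r)))
  y <- y * env
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y * (target_rms / rms)
  y
}

#' Simulate a multichannel cyclostationary sEMG recording
#'
#' Places one activity burst per pedal revolution on each channel, with
#' muscle-specific within-cycle phase offsets (the left leg half a cycle out
#' of phase with the right), onset jitter, exertion-driven amplitude and
#' spectral-tail drift, and white baseline noise.  All randomness comes from
#' `seed`: identical arguments give bit-identical output.
#'
#' @param protocol An `emg_protocol`.
#' @param truth A `metabolic_truth` from [simulate_metabolics()] (supplies
#'   the latent exertion trajectory), or `NULL` for constant exertion 1.
#' @param channels Character vector of `"<muscle>_<side>"` labels.
#' @param params An `emg_params` list.
#' @param seed Integer seed.
#'
#' @return A list of class `emg_sim`:
#'   * `emg`: tibble with `time_s` and one numeric column per channel (mV);
#'   * `onsets`: tibble (`channel`, `cycle`, `onset_time_s`, `onset_sample`)
#'     of ground-truth burst onsets;
#'   * `params`, `protocol`.
#' @export
#' @examples
#' pr <- protocol_spec(data.frame(duration_s = 4, load_frac = 0.6))
#' sim <- simulate_emg(pr, truth = NULL, channels = "VL_right", seed = 1)
#' nrow(sim$emg)
simulate_emg <- function(protocol,
                         truth = NULL,
                         channels = default_channels(),
                         params = emg_params(),
                         seed = 1L) {
  stopifnot(inherits(protocol, "emg_protocol"))
  if (!inherits(params, "emg_params")) params <- do.call(emg_params, params)
  for (ch in channels) parse_channel_label(ch)

  fs <- protocol$sampling_rate_hz
  cycle_s <- 60 / protocol$cadence_rpm
  burst_s <- params$burst_frac * cycle_s
  if (burst_s >= cycle_s) abort("burst duration must be shorter than the pedal cycle")
  n <- round(protocol$total_s * fs)
  lb <- max(8L, round(burst_s * fs))

  exertion_at <- if (is.null(truth)) {
    function(t) rep(1, length(t))
  } else {
    stopifnot(inherits(truth, "metabolic_truth"))
    function(t) {
      stats::approx(truth$latent$time_s, truth$latent$exertion,
        xout = t, rule = 2
      )$y
    }
  }

  withr::with_seed(seed, {
    sig <- matrix(0, nrow = n, ncol = length(channels))
    onset_list <- vector("list", length(channels))
    for (j in seq_along(channels)) {
      lab <- parse_channel_label(channels[j])
      phase <- .muscle_phase[[lab$muscle]] + if (lab$side == "left") 0.5 else 0
      offset_s <- (phase %% 1) * cycle_s
      k_max <- floor((protocol$total_s - offset_s - burst_s) / cycle_s)
      if (k_max < 0) abort("protocol too short for a single burst")
      base <- offset_s + (0:k_max) * cycle_s
      jit <- if (params$jitter_s > 0) {
        runif(length(base), -params$jitter_s, params$jitter_s)
      } else {
        0
      }
      onsets_s <- base + jit
      onsets_s <- onsets_s[onsets_s >= 0 & onsets_s + burst_s <= protocol$total_s]
      x <- if (params$noise_sd_mv > 0) rnorm(n, 0, params$noise_sd_mv) else numeric(n)
      ex <- exertion_at(onsets_s)
      tail_w <- pmin(0.95, pmax(
        0.02,
        params$tail_mass + params$tail_drift * ex
      ))
      rms <- params$amp_base_mv * (0.25 + params$amp_gain * ex)
      i0 <- round(onsets_s * fs) + 1L
      for (k in seq_along(onsets_s)) {
        idx <- i0[k]:(i0[k] + lb - 1L)
        x[idx] <- x[idx] + make_burst(lb, fs, params, tail_w[k], rms[k])
      }
      sig[, j] <- x
      onset_list[[j]] <- tibble::tibble(
        channel = channels[j],
        cycle = seq_along(onsets_s),
        onset_time_s = onsets_s,
        onset_sample = i0
      )
    }
    emg <- tibble::as_tibble(as.data.frame(sig))
    names(emg) <- channels
    emg <- dplyr::bind_cols(tibble::tibble(time_s = (seq_len(n) - 1) / fs), emg)
    structure(
      list(
        emg = emg,
        onsets = dplyr::bind_rows(onset_list),
        params = params,
        protocol = protocol
      ),
      class = "emg_sim"
    )
  })
}

#' @export
print.emg_sim <- function(x, ...) {
  cat(sprintf(
    "<emg_sim> %d samples x %d channel(s), %d ground-truth bursts\n",
    nrow(x$emg), ncol(x$emg) - 1L, nrow(x$onsets)
  ))
  invisible(x)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: metabolic trajectories plus a coupled multichannel
#' EMG recording for one synthetic "subject".
#'
#' @inheritParams simulate_emg
#' @param metabolic A `metabolic_params` list.
#' @return List with `truth` (`metabolic_truth`) and `sim` (`emg_sim`).
#' @export
simulate_dataset <- function(protocol = default_protocol(),
                             channels = default_channels(),
                             metabolic = metabolic_params(),
                             params = emg_params(),
                             seed = 1L) {
  truth <- simulate_metabolics(protocol, metabolic, seed = seed)
  sim <- simulate_emg(protocol, truth, channels, params, seed = seed + 1L)
  list(truth = truth, sim = sim)
}
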