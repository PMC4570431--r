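#' Define a constant-load exercise protocol
#'
#' A protocol is a sequence of constant-load phases ridden at a fixed pedal
#' cadence.  Loads are expressed as fractions of the rider's maximal aerobic
#' (VO2max) power, so `load_frac = 0.6` means cycling at 60% of VO2max power.
#'
#' @param phases Data frame with columns `duration_s` (phase length, seconds,
#'   > 0) and `load_frac` (fraction of VO2max power, in (0, 1.2]).
#' @param cadence_rpm Pedal cadence in revolutions per minute (> 0; the
#'   protocol this package emulates prescribes 90-100 rpm).
#' @param sampling_rate_hz EMG sampling rate in Hz (default 1000).
#'
#' @return An object of class `emg_protocol`: a list with elements `phases`
#'   (tibble), `cadence_rpm`, `sampling_rate_hz`, and derived `total_s`.
#' @export
#' @examples
#' protocol_spec(data.frame(duration_s = c(60, 60), load_frac = c(0.6, 0.9)))
protocol_spec <- function(phases, cadence_rpm = 90, sampling_rate_hz = 1000) {
  phases <- tibble::as_tibble(phases)
  if (!all(c("duration_s", "load_frac") %in% names(phases))) {
    abort("`phases` needs columns duration_s and load_frac")
  }
  if (nrow(phases) == 0) abort("protocol needs at least one phase")
  if (any(phases$duration_s <= 0)) abort("phase durations must be > 0")
  if (any(phases$load_frac <= 0 | phases$load_frac > 1.2)) {
    abort("load_frac must lie in (0, 1.2]")
  }
  if (cadence_rpm <= 0) abort("cadence_rpm must be > 0")
  if (sampling_rate_hz <= 0) abort("sampling_rate_hz must be > 0")
  structure(
    list(
      phases = phases[c("duration_s", "load_frac")],
      cadence_rpm = cadence_rpm,
      sampling_rate_hz = sampling_rate_hz,
      total_s = sum(phases$duration_s)
    ),
    class = "emg_protocol"
  )
}

#' Default three-phase constant-load protocol
#'
#' Six minutes at 60% of VO2max power, a high-intensity phase at ~92.5%
#' (midpoint of the prescribed 90-95% band) ridden until exhaustion -- here a
#' fixed 300 s, a typical time to task failure at that intensity -- and six
#' minutes of active recovery at 60%.
#'
#' @inheritParams protocol_spec
#' @return An `emg_protocol` object.
#' @export
default_protocol <- function(cadence_rpm = 90, sampling_rate_hz = 1000) {
  protocol_spec(
    tibble::tibble(
      duration_s = c(360, 300, 360),
      load_frac = c(0.60, 0.925, 0.60)
    ),
    cadence_rpm = cadence_rpm,
    sampling_rate_hz = sampling_rate_hz
  )
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat(sprintf(
    "<emg_protocol> %d phase(s), %.0f s total, %.0f rpm, fs = %g Hz\n",
    nrow(x$phases), x$total_s, x$cadence_rpm, x$sampling_rate_hz
  ))
  print(x$phases)
  invisible(x)
}

#' Load fraction at given times
#'
#' Evaluates the protocol's piecewise-constant load profile.  Times at or
#' beyond the protocol end take the last phase's load.
#'
#' @param protocol An `emg_protocol`.
#' @param times_s Numeric vector of times in seconds (>= 0).
#' @return Numeric vector of load fractions.
#' @export
load_profile <- function(protocol, times_s) {
  stopifnot(inherits(protocol, "emg_protocol"))
  edges <- c(0, cumsum(protocol$phases$duration_s))
  idx <- findInterval(times_s, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(protocol$phases)] <- nrow(protocol$phases)
  protocol$phases$load_frac[idx]
}
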