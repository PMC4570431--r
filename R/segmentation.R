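#' Backward difference of a signal
#'
#' `delta[t] = s[t] - s[t-1]`; the result is one sample shorter than the
#' input.
#'
#' @param s Numeric vector, length >= 2.
#' @return Numeric vector of length `length(s) - 1`.
#' @export
#' @examples
#' backward_difference(c(1, 3, 6))
backward_difference <- function(s) {
  if (length(s) < 2) abort("signal must have at least 2 samples")
  diff(s)
}

#' Windowed variability of a differenced signal
#'
#' Sliding-window sum of the backward difference over windows of `n`
#' samples: `V[t] = sum(|delta[t..t+n-1]|)` in the default `"absolute"`
#' mode, a windowed total variation that is large inside an activity burst
#' and small in the inter-burst baseline.  The `"signed"` mode sums the raw
#' differences instead; that sum telescopes to a two-point difference
#' `s[t+n] - s[t]` and does not measure variability, so it is kept only for
#' comparison.
#'
#' @param delta Numeric vector of backward differences.
#' @param n Window length in samples (default 256).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Numeric vector of length `length(delta) - n + 1`; element `t` is
#'   the variability of the window starting at `delta[t]`.
#' @export
variability <- function(delta, n = 256, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (n < 1) abort("n must be >= 1")
  if (length(delta) < n) abort("signal shorter than the window")
  x <- if (mode == "absolute") abs(delta) else delta
  cs <- cumsum(x)
  len <- length(x)
  cs[n:len] - c(0, cs[seq_len(len - n)])
}

#' Variability ratio around each time point
#'
#' Compares the variability of the `n`-sample window ending just before
#' each point with the window starting at it:
#' `Vcom[t] = V[t - n] / V[t]`.  At a burst onset the trailing window is
#' quiet and the leading window active, so `Vcom` attains a local minimum;
#' at a burst end it attains a local maximum.  The denominator is guarded
#' by `eps` so the ratio is finite even over silent stretches.
#'
#' @param v Variability from [variability()].
#' @param n Window length used to compute `v`.
#' @param eps Denominator guard; default `max(v) * 1e-12` (scales with the
#'   signal, so onset detection is amplitude-invariant).
#' @return Numeric vector of length `length(v) - n`; element `i`
#'   corresponds to split point `t = i + n` of `v`, i.e. signal sample
#'   `i + n` (stored in attribute `offset`).
#' @export
variability_ratio <- function(v, n = 256, eps = NULL) {
  if (length(v) <= n) abort("variability vector shorter than one window offset")
  if (is.null(eps)) eps <- max(v) * 1e-12
  eps <- max(eps, .Machine$double.xmin)
  t <- (n + 1):length(v)
  out <- v[t - n] / pmax(v[t], eps)
  attr(out, "offset") <- n
  out
}

# Local-minimum runs of x (plateau-aware).  Returns the index of the LAST
# element of each interior run whose value is below both neighbouring runs;
# taking the right edge of a flat minimum puts the onset at the point where
# the leading window first picks up burst energy.
local_min_runs <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 2) {
    return(integer(0))
  }
  ends <- cumsum(r$lengths)
  if (k == 2) {
    return(if (r$values[1] < r$values[2]) ends[1] else integer(0))
  }
  # the first run may be a minimum (a burst can start right at the recording
  # head); the last run may not (no segment could be cut there anyway)
  is_min <- c(
    r$values[1] < r$values[2],
    r$values[2:(k - 1)] < r$values[1:(k - 2)] &
      r$values[2:(k - 1)] < r$values[3:k],
    FALSE
  )
  ends[is_min]
}

#' Detect burst onsets from the variability ratio
#'
#' Onset candidates are the local minima of `Vcom` (plateaus count once, at
#' their right edge) with `Vcom <= max_onset_ratio`.  Candidates are
#' thinned so no two onsets are closer than `min_separation_samples`
#' (deeper minima win), kept only if they dip at least `prominence_frac`
#' below the lower of their enclosing maxima (relative to that maximum),
#' and finally refined to the right edge of their flat valley, where the
#' leading-window variability starts to rise.
#'
#' @param vcom Numeric vector from [variability_ratio()].
#' @param min_separation_samples Minimum distance between onsets, in
#'   samples; a natural default is 0.7 of the expected pedal-cycle length.
#' @param prominence_frac Required relative prominence: the fraction by
#'   which the minimum must dip below its enclosing barrier (default 0.2).
#' @param max_onset_ratio Largest `Vcom` value an onset may have (default
#'   0.5): at a genuine burst onset the leading window is substantially
#'   more variable than the trailing one, so `Vcom` is well below 1;
#'   shallow dips of a noise-only stretch hover near 1 and are rejected.
#' @return Sorted integer indices into `vcom` (add the `offset` attribute
#'   of `vcom` to get signal sample indices, as [segment_emg()] does).
#' @export
detect_onsets <- function(vcom, min_separation_samples, prominence_frac = 0.2,
                          max_onset_ratio = 0.5) {
  if (length(vcom) == 0 || !all(is.finite(vcom))) {
    abort("vcom must be non-empty and finite")
  }
  rng <- max(vcom) - min(vcom)
  if (rng == 0) {
    return(integer(0))
  }
  cand <- local_min_runs(as.numeric(vcom))
  cand <- cand[vcom[cand] <= max_onset_ratio]
  if (length(cand) == 0) {
    return(integer(0))
  }

  # min-separation suppression first, deepest minima winning; this thins the
  # many shallow micro-minima on a valley floor down to one onset per cycle
  ord <- cand[order(vcom[cand])]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= min_separation_samples)) keep <- c(keep, i)
  }
  keep <- sort(keep)

  # relative prominence of each retained minimum: it must dip at least
  # prominence_frac below the lower of its two enclosing maxima, relative to
  # that maximum.  A ratio signal like Vcom is heavy-tailed, so the dip is
  # judged against the local barrier, not the global range.
  bounds <- c(1L, keep, length(vcom))
  prom <- vapply(seq_along(keep), function(i) {
    v <- vcom[keep[i]]
    left <- max(vcom[bounds[i]:keep[i]])
    right <- max(vcom[keep[i]:bounds[i + 2]])
    # a side on which no point could ever satisfy the dip criterion is a
    # clipped valley edge (e.g. at the vector head), not a barrier, and is
    # ignored rather than scored
    sides <- c(left, right)
    sides <- sides[sides * (1 - prominence_frac) > v]
    if (length(sides) == 0) 0 else (min(sides) - v) / min(sides)
  }, numeric(1))
  keep <- keep[prom >= prominence_frac]

  # refine each onset to the right edge of its flat valley: under noise the
  # argmin wanders across the quiet stretch before the burst, while the true
  # onset is where Vcom starts to rise (the leading window filling with
  # burst energy).  Walk right while values stay within 15% of the minimum.
  refined <- vapply(keep, function(i) {
    thr <- vcom[i] * 1.15
    j <- i
    lim <- min(length(vcom), i + min_separation_samples)
    while (j < lim) {
      if (vcom[j + 1] <= thr) {
        j <- j + 1
      } else if (j + 2 <= lim && vcom[j + 2] <= thr) {
        j <- j + 2 # step over an isolated noise bump
      } else {
        break
      }
    }
    # a minimum never followed by a rise (walk ran into the vector end) is
    # a clipped valley with no burst behind it, not an onset
    if (j >= length(vcom)) NA_integer_ else as.integer(j)
  }, integer(1))
  refined[!is.na(refined)]
}

#' Cut fixed-length segments at detected onsets
#'
#' Segment `i` is `s[onset_i .. onset_i + n - 1]`.  Onsets whose window
#' would overrun the signal are dropped with a message.
#'
#' @param s Numeric signal vector (the filtered EMG channel).
#' @param onsets Integer sample indices (1-based segment starts).
#' @param n Segment length in samples (default 256).
#' @return Tibble with columns `onset_sample` and `segment` (list column of
#'   length-`n` numeric vectors).
#' @export
extract_segments <- function(s, onsets, n = 256) {
  onsets <- sort(as.integer(onsets))
  fits <- onsets + n - 1L <= length(s)
  if (any(!fits)) {
    inform(sprintf("dropping %d onset(s) whose %d-sample window overruns the signal", sum(!fits), n))
  }
  onsets <- onsets[fits]
  tibble::tibble(
    onset_sample = onsets,
    segment = lapply(onsets, function(o) s[o:(o + n - 1L)])
  )
}

# Variability ratio over the whole recording, with the trailing (numerator)
# window allowed to truncate at the recording start.  Truncated windows are
# length-normalised (scaled to a full-window-equivalent sum), which leaves
# the interior values identical to variability_ratio() but lets bursts in
# the first 2N samples be detected instead of falling outside the defined
# range.  Element i of the result corresponds to signal sample i + 1
# (attribute `offset` = 1).
vcom_edge_aware <- function(s, n = 256, mode = "absolute") {
  d <- backward_difference(s)
  x <- if (mode == "absolute") abs(d) else d
  nd <- length(x)
  if (nd < n + 1) abort("signal too short for one full leading window")
  cs <- c(0, cumsum(x))
  t_min <- max(2L, ceiling(n / 2) + 1L) # demand solid trailing-window support
  t <- t_min:(nd - n + 1)
  den <- cs[t + n] - cs[t] # full window d[t .. t+n-1]
  lo <- pmax(1, t - n)
  m <- t - lo # truncated window d[lo .. t-1]
  num <- (cs[t] - cs[lo]) * (n / m)
  eps <- max(max(den) * 1e-12, .Machine$double.xmin)
  out <- num / pmax(den, eps)
  attr(out, "offset") <- t_min - 1L
  out
}

#' Segment every channel of an EMG recording
#'
#' Runs the full variability-ratio pipeline (backward difference, windowed
#' variability, before/after ratio, local-minimum onset detection) on each
#' channel and cuts `n`-sample segments of the filtered signal at the
#' detected onsets.
#'
#' @param emg Filtered EMG tibble (see [bandpass_emg()]).
#' @param cadence_rpm Expected pedal cadence; sets the default minimum
#'   onset separation (`min_separation_frac` of a cycle).
#' @param n Window/segment length in samples (default 256, i.e. 256 ms at
#'   1000 Hz, about a third of a pedal cycle).
#' @param min_separation_frac Minimum onset separation as a fraction of the
#'   expected cycle length (default 0.7).
#' @param prominence_frac Passed to [detect_onsets()].
#' @param max_onset_ratio Passed to [detect_onsets()].
#' @param mode Variability mode, see [variability()].
#' @return Tibble with one row per detected segment: `channel`,
#'   `onset_sample`, `onset_time_s`, `segment` (list of length-`n` numeric
#'   vectors).
#' @export
#' @examples
#' pr <- protocol_spec(data.frame(duration_s = 5, load_frac = 0.6))
#' sim <- simulate_emg(pr, NULL, "VL_right", seed = 2)
#' seg <- segment_emg(bandpass_emg(sim$emg), cadence_rpm = 90)
#' nrow(seg)
segment_emg <- function(emg, cadence_rpm = 90, n = 256,
                        min_separation_frac = 0.7, prominence_frac = 0.2,
                        max_onset_ratio = 0.5, mode = "absolute") {
  validate_emg(emg)
  fs <- emg_sampling_rate(emg)
  cycle_samples <- fs * 60 / cadence_rpm
  min_sep <- round(min_separation_frac * cycle_samples)
  channels <- setdiff(names(emg), "time_s")

  purrr::map_dfr(channels, function(ch) {
    s <- emg[[ch]]
    vcom <- vcom_edge_aware(s, n, mode)
    idx <- detect_onsets(vcom, min_sep, prominence_frac, max_onset_ratio)
    if (length(idx) == 0) {
      return(tibble::tibble(
        channel = character(0), onset_sample = integer(0),
        onset_time_s = numeric(0), segment = list()
      ))
    }
    onsets <- idx + attr(vcom, "offset")
    seg <- extract_segments(s, onsets, n)
    tibble::tibble(
      channel = ch,
      onset_sample = seg$onset_sample,
      onset_time_s = emg$time_s[seg$onset_sample],
      segment = seg$segment
    )
  })
}
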