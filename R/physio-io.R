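#' Write / read a multichannel EMG recording as CSV
#'
#' The on-disk format is a plain CSV with a `time_s` column followed by one
#' column per channel, named `"<muscle>_<side>"`.  Doubles are written with
#' shortest round-trip precision, so `read_emg(write_emg(x))` reproduces `x`
#' exactly.
#'
#' @param emg Tibble with a strictly increasing `time_s` column and one or
#'   more numeric channel columns.
#' @param path File path.
#' @return `write_emg()` returns `emg` invisibly; `read_emg()` returns the
#'   tibble.
#' @export
write_emg <- function(emg, path) {
  validate_emg(emg)
  readr::write_csv(full_precision(emg), path)
  invisible(emg)
}

# Format doubles with 17 significant digits so write -> read is exact.
full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  # base read.csv: its strtod parsing is correctly rounded, so files written
  # with 17 significant digits round-trip bit-exactly
  emg <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) abort(sprintf("malformed EMG file '%s': %s", path, conditionMessage(e)))
  )
  if (!all(vapply(emg, is.numeric, logical(1)))) {
    abort(sprintf("malformed EMG file '%s' (non-numeric cells)", path))
  }
  emg <- tibble::as_tibble(emg)
  validate_emg(emg)
  emg
}

validate_emg <- function(emg) {
  if (!"time_s" %in% names(emg)) abort("EMG table needs a time_s column")
  channels <- setdiff(names(emg), "time_s")
  if (length(channels) == 0) abort("EMG table has no channel columns")
  for (ch in channels) parse_channel_label(ch)
  if (anyNA(emg)) abort("EMG table contains missing values")
  if (any(diff(emg$time_s) <= 0)) abort("time_s must be strictly increasing")
  invisible(emg)
}

#' Sampling rate of an EMG tibble
#'
#' @param emg Tibble with a `time_s` column on a uniform grid.
#' @return Sampling rate in Hz.
#' @export
emg_sampling_rate <- function(emg) {
  dt <- diff(emg$time_s)
  if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
    warn("time_s grid is not uniform; using the median step")
  }
  1 / stats::median(dt)
}

#' Write / read a sparse physiological series as CSV
#'
#' Two-column CSV `time_s,value`; `kind` ("lactate" or "vo2") travels as an
#' attribute, not in the file.
#'
#' @param series Tibble with strictly increasing `time_s` and numeric
#'   `value`.
#' @param path File path.
#' @param kind Measurement kind, `"lactate"` (mmol/L) or `"vo2"` (L/min).
#' @return The physio tibble (invisibly for the writer).
#' @export
write_physio <- function(series, path) {
  validate_physio(series)
  readr::write_csv(full_precision(series[c("time_s", "value")]), path)
  invisible(series)
}

#' @rdname write_physio
#' @export
read_physio <- function(path, kind = c("lactate", "vo2")) {
  kind <- match.arg(kind)
  s <- tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
  validate_physio(s)
  attr(s, "kind") <- kind
  s
}

validate_physio <- function(series) {
  if (!all(c("time_s", "value") %in% names(series))) {
    abort("physio series needs time_s and value columns")
  }
  if (anyNA(series$time_s) || anyNA(series$value)) {
    abort("physio series contains missing values")
  }
  if (nrow(series) < 2) abort("physio series needs at least 2 points")
  if (any(diff(series$time_s) <= 0)) abort("time_s must be strictly increasing")
  invisible(series)
}

#' Cubic Hermite interpolation with Catmull-Rom tangents
#'
#' Interpolates a sparse series at arbitrary in-range query times with a C1
#' piecewise-cubic Hermite spline whose tangent at interior knot i is the
#' centred finite difference `(v[i+1] - v[i-1]) / (t[i+1] - t[i-1])`
#' (the Catmull-Rom rule generalised to non-uniform spacing); endpoint
#' tangents are one-sided differences.  The interpolant passes through every
#' knot exactly and reproduces linear data exactly.  Queries outside the
#' knot range are an error: extrapolating physiology is not meaningful.
#'
#' @param series Tibble with `time_s` (strictly increasing, >= 2 knots) and
#'   `value` columns, e.g. from [read_physio()].
#' @param query_times_s Numeric vector of times within
#'   `range(series$time_s)`.
#' @return Numeric vector of interpolated values, one per query time.
#' @export
#' @examples
#' s <- tibble::tibble(time_s = c(0, 60, 120), value = c(1, 2, 1.5))
#' interpolate_catmull_rom(s, c(0, 30, 90))
interpolate_catmull_rom <- function(series, query_times_s) {
  validate_physio(series)
  t <- series$time_s
  v <- series$value
  n <- length(t)
  if (any(query_times_s < t[1] - 1e-12) || any(query_times_s > t[n] + 1e-12)) {
    abort("query times outside the knot range; extrapolation is not supported")
  }
  q <- pmin(pmax(query_times_s, t[1]), t[n])

  # knot tangents: centred differences inside, one-sided at the ends
  m <- numeric(n)
  if (n == 2) {
    m[] <- (v[2] - v[1]) / (t[2] - t[1])
  } else {
    m[1] <- (v[2] - v[1]) / (t[2] - t[1])
    m[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    m[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }

  k <- findInterval(q, t, rightmost.closed = TRUE)
  k[k < 1] <- 1L
  k[k >= n] <- n - 1L
  h <- t[k + 1] - t[k]
  u <- (q - t[k]) / h
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  h00 * v[k] + h10 * h * m[k] + h01 * v[k + 1] + h11 * h * m[k + 1]
}
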