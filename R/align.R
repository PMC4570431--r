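#' Align a physiological series to segment timestamps
#'
#' Interpolates the sparse physiological measurements (Catmull-Rom Hermite
#' spline, see [interpolate_catmull_rom()]) at every segment timestamp and
#' appends the result as the target column.  Targets are interpolated to
#' segment times -- rather than features aggregated to measurement times --
#' to preserve the per-revolution sampling density the models are built on.
#' Segments outside the measured time span are dropped with a message
#' (extrapolating physiology is not supported).
#'
#' @param features Feature tibble with a `time_s` column, e.g. from
#'   [median_smooth()].
#' @param physio Physio tibble (`time_s`, `value`), e.g. from
#'   [read_physio()] or [simulate_metabolics()].
#' @param target Name for the appended target column (`"lactate"` or
#'   `"vo2"`).
#' @return The feature tibble with rows restricted to the physio span and a
#'   new `target` column.
#' @export
align_features <- function(features, physio, target = "lactate") {
  validate_physio(physio)
  lo <- min(physio$time_s)
  hi <- max(physio$time_s)
  inside <- features$time_s >= lo & features$time_s <= hi
  if (!any(inside)) abort("no segment timestamps fall inside the physio series span")
  if (any(!inside)) {
    inform(sprintf(
      "dropping %d segment(s) outside the physio span [%g, %g] s",
      sum(!inside), lo, hi
    ))
  }
  out <- features[inside, , drop = FALSE]
  out[[target]] <- interpolate_catmull_rom(physio, out$time_s)
  out
}
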