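#' Fit a z-score scaler on training data
#'
#' Records per-column mean and standard deviation of the selected numeric
#' columns.  Zero-variance columns are dropped with a warning (a constant
#' has no z-score).  Always fit on training rows only and applied to any
#' rows, so no information leaks from validation folds.
#'
#' @param data Data frame of predictors (numeric columns are used).
#' @param cols Columns to scale; default all numeric columns.
#' @return Object of class `cyclemg_scaler`.
#' @export
fit_scaler <- function(data, cols = NULL) {
  if (nrow(data) < 2) abort("need at least 2 rows to fit a scaler")
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  mu <- vapply(cols, function(cl) mean(data[[cl]]), numeric(1))
  sig <- vapply(cols, function(cl) sd(data[[cl]]), numeric(1))
  dropped <- cols[sig == 0 | is.na(sig)]
  if (length(dropped) > 0) {
    warn(paste0(
      "dropping zero-variance column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  keep <- setdiff(cols, dropped)
  structure(
    list(cols = keep, mean = mu[keep], sd = sig[keep], dropped = dropped),
    class = "cyclemg_scaler"
  )
}

#' Apply (or invert) a fitted scaler
#'
#' @param data Data frame containing the scaler's columns.
#' @param scaler A `cyclemg_scaler` from [fit_scaler()].
#' @param inverse If `TRUE`, map z-scores back to original units.
#' @return Tibble with the scaler's columns transformed (dropped columns
#'   removed).
#' @export
apply_scaler <- function(data, scaler, inverse = FALSE) {
  stopifnot(inherits(scaler, "cyclemg_scaler"))
  out <- tibble::as_tibble(data)
  out <- out[, setdiff(names(out), scaler$dropped), drop = FALSE]
  for (cl in scaler$cols) {
    out[[cl]] <- if (inverse) {
      data[[cl]] * scaler$sd[[cl]] + scaler$mean[[cl]]
    } else {
      (data[[cl]] - scaler$mean[[cl]]) / scaler$sd[[cl]]
    }
  }
  out
}
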