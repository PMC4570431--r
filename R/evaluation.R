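#' Spearman's rank correlation
#'
#' Rank correlation between two vectors: +1 for any strictly increasing
#' monotone relationship, -1 for strictly decreasing.  Ties receive average
#' ranks and the coefficient is the Pearson correlation of the ranks (on
#' tie-free data this equals the classical closed form
#' `1 - 6 sum(d^2) / (n (n^2 - 1))`).  A constant input has no ranks to
#' correlate; the result is `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' spearman_cor(1:10, (1:10)^3) # exactly 1
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  r <- stats::cor(x, y, method = "spearman")
  # purely monotone data must give exactly +-1; snap float fuzz on ranks
  if (1 - abs(r) < 1e-12) r <- sign(r)
  r
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`: 1 for a perfect
#' predictor, 0 for the mean predictor, negative for predictors worse than
#' the mean.  A constant `y` (zero denominator) returns 0 with a warning.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return A single number <= 1.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("y and y_hat must have equal length")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warn("constant y: R^2 undefined, returning 0")
    return(0)
  }
  1 - sum((y - y_hat)^2) / ss_tot
}

#' k-fold cross-validated R^2
#'
#' Splits the rows into `k` disjoint folds (random by default, optionally
#' time-contiguous), fits the model on each training split -- including the
#' z-score scaler for ridge, fit on training rows only -- and scores
#' predictions on the held-out fold.  The fold assignment is independent of
#' any folds used inside shrinkage selection.
#'
#' @param data Data frame with predictors and the response.
#' @param response Name of the response column.
#' @param model `"ridge"` or `"forest"`.
#' @param k Number of folds (default 10; must not exceed `nrow(data)`).
#' @param seed Integer seed for the fold assignment (and forest fits).
#' @param contiguous If `TRUE`, folds are consecutive time blocks instead
#'   of random.
#' @param lambda Shrinkage for `model = "ridge"`.
#' @param n_trees,mtry Forest parameters for `model = "forest"`.
#' @param predictors Optional predictor names.
#' @return List with `mean_r2` and `folds` (tibble `fold`, `n_test`, `r2`).
#' @export
kfold_cv <- function(data, response, model = c("ridge", "forest"),
                     k = 10, seed = 1L, contiguous = FALSE,
                     lambda = 32, n_trees = 100, mtry = NULL,
                     predictors = NULL) {
  model <- match.arg(model)
  ids <- fold_ids(nrow(data), k, seed, contiguous)
  folds <- purrr::map_dfr(seq_len(k), function(fold) {
    tr <- data[ids != fold, , drop = FALSE]
    te <- data[ids == fold, , drop = FALSE]
    fit <- if (model == "ridge") {
      withCallingHandlers(
        ridge_fit(tr, response, lambda, predictors = predictors),
        warning = function(w) invokeRestart("muffleWarning")
      )
    } else {
      forest_fit(tr, response,
        n_trees = n_trees, mtry = mtry,
        seed = seed + fold, predictors = predictors
      )
    }
    tibble::tibble(
      fold = fold, n_test = nrow(te),
      r2 = r_squared(te[[response]], predict(fit, te))
    )
  })
  list(mean_r2 = mean(folds$r2), folds = folds)
}

#' Quantile-segment summary of per-dataset weights or importances
#'
#' For each variable, the 0/0.2/0.4/0.6/0.8/1 quantiles of its values
#' across datasets (the stacked-segment display used for weight and
#' importance distributions) plus a two-sided one-sample t-test of whether
#' the mean differs from zero.  With fewer than 3 values per variable no
#' test is run.  Zero-variance values are handled by convention: a nonzero
#' constant is flagged significant (with a warning), a zero constant is
#' not.
#'
#' @param data Data frame with one row per (dataset, variable) value.
#' @param variable Name of the grouping column (default `"variable"`).
#' @param value Name of the value column (default `"value"`).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble with one row per variable: `q0`, `q20`, `q40`, `q60`,
#'   `q80`, `q100`, `n`, `p_value`, `significant`.
#' @export
summarize_distribution <- function(data, variable = "variable",
                                   value = "value", alpha = 0.05) {
  data |>
    dplyr::group_by(.data[[variable]]) |>
    dplyr::group_modify(function(d, key) {
      v <- d[[value]]
      qs <- quantile(v, probs = seq(0, 1, by = 0.2), names = FALSE)
      if (length(v) < 3) {
        p <- NA_real_
        sig <- NA
      } else if (sd(v) == 0) {
        if (v[1] != 0) {
          warn("zero-variance values: degenerate t-test, flagged significant by convention")
          p <- 0
          sig <- TRUE
        } else {
          p <- 1
          sig <- FALSE
        }
      } else {
        p <- t.test(v, mu = 0)$p.value
        sig <- p < alpha
      }
      tibble::tibble(
        q0 = qs[1], q20 = qs[2], q40 = qs[3], q60 = qs[4], q80 = qs[5],
        q100 = qs[6], n = length(v), p_value = p, significant = sig
      )
    }) |>
    dplyr::ungroup()
}

#' Paired comparison of two models' per-dataset R^2
#'
#' Two-sided paired t-test on the per-dataset differences in R^2 (e.g.
#' forest minus ridge across channels), the test used to establish that
#' non-linear models outperform linear ones.
#'
#' @param r2_a,r2_b Equal-length numeric vectors of per-dataset R^2.
#' @return Tibble with `mean_diff`, `t`, `df`, `p_value`.  Zero-variance
#'   differences make the test undefined: `p_value` is `NA` with a
#'   warning.
#' @export
paired_model_comparison <- function(r2_a, r2_b) {
  if (length(r2_a) != length(r2_b)) abort("vectors must have equal length")
  if (length(r2_a) < 2) abort("need at least 2 paired datasets")
  d <- r2_a - r2_b
  if (sd(d) == 0) {
    warn("zero-variance differences: paired t-test undefined")
    return(tibble::tibble(
      mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
      p_value = NA_real_
    ))
  }
  tt <- t.test(r2_a, r2_b, paired = TRUE)
  tibble::tibble(
    mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value
  )
}
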