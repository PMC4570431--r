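# Numeric predictor columns of a feature table (everything numeric except
# the response and bookkeeping columns).
predictor_cols <- function(data, response) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, c(response, "time_s", "onset_sample", "cycle", "segment"))
}

#' Ridge regression on z-scored variables
#'
#' Fits the linear model `y_hat = x' beta` on z-scores of the predictors and
#' the response (both standardised on the supplied data, so no intercept is
#' needed), with Tikhonov (ridge) shrinkage: `beta` minimises
#' `sum((y - X beta)^2) + lambda * sum(beta^2)`, i.e. solves
#' `(X'X + lambda I) beta = X'y`.  Because predictors are z-scored, the
#' magnitude of a weight measures the influence of its variable.
#'
#' @param data Data frame with predictor columns and the response.
#' @param response Name of the response column (e.g. `"lactate"`).
#' @param lambda Shrinkage parameter, >= 0.
#' @param predictors Predictor column names; default all numeric columns
#'   except the response and bookkeeping columns.
#' @return Object of class `cyclemg_ridge` with standardized weights
#'   (`beta`), the scalers, and `lambda`.  Supports `predict()`, [tidy()]
#'   and [glance()].
#' @export
#' @examples
#' d <- data.frame(a = rnorm(20), b = rnorm(20))
#' d$y <- d$a + 0.5 * d$b + rnorm(20, sd = 0.1)
#' fit <- ridge_fit(d, "y", lambda = 1)
#' tidy(fit)
ridge_fit <- function(data, response, lambda, predictors = NULL) {
  if (lambda < 0) abort("lambda must be >= 0")
  if (nrow(data) < 2) abort("need at least 2 rows")
  predictors <- predictors %||% predictor_cols(data, response)
  xs <- fit_scaler(data, predictors)
  y <- data[[response]]
  y_mu <- mean(y)
  y_sd <- sd(y)
  if (y_sd == 0) {
    warn("constant response: all weights are zero")
    y_sd <- 1
  }
  x <- as.matrix(apply_scaler(data, xs)[, xs$cols, drop = FALSE])
  yz <- (y - y_mu) / y_sd

  a <- crossprod(x) + diag(lambda, ncol(x))
  b <- crossprod(x, yz)
  beta <- tryCatch(
    drop(solve(a, b)),
    error = function(e) {
      abort("penalized system is singular (collinear predictors at lambda = 0); use lambda > 0")
    }
  )
  structure(
    list(
      beta = stats::setNames(beta, xs$cols),
      lambda = lambda,
      x_scaler = xs,
      y_mean = y_mu, y_sd = y_sd,
      response = response,
      n = nrow(data)
    ),
    class = "cyclemg_ridge"
  )
}

#' @export
predict.cyclemg_ridge <- function(object, newdata, ...) {
  x <- as.matrix(
    apply_scaler(newdata, object$x_scaler)[, object$x_scaler$cols, drop = FALSE]
  )
  drop(x %*% object$beta) * object$y_sd + object$y_mean
}

#' @export
print.cyclemg_ridge <- function(x, ...) {
  cat(sprintf(
    "<cyclemg_ridge> %s ~ %d predictors, lambda = %g, n = %d\n",
    x$response, length(x$beta), x$lambda, x$n
  ))
  invisible(x)
}

#' @rdname ridge_fit
#' @param x A fitted `cyclemg_ridge`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cyclemg_ridge <- function(x, ...) {
  tibble::tibble(variable = names(x$beta), weight = unname(x$beta))
}

#' @rdname ridge_fit
#' @exportS3Method generics::glance
glance.cyclemg_ridge <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n = x$n, p = length(x$beta), response = x$response
  )
}

# Disjoint k-fold assignment covering all rows.
fold_ids <- function(n, k, seed, contiguous = FALSE) {
  if (k > n) abort("k must not exceed the number of rows")
  ids <- rep(seq_len(k), length.out = n)
  if (contiguous) {
    sort(ids)
  } else {
    withr::with_seed(seed, sample(ids))
  }
}

# Mean k-fold CV R^2 of ridge at each lambda, computed efficiently via one
# SVD per training fold: beta(lambda) = V diag(d/(d^2+lambda)) U'y.
ridge_cv_curve <- function(data, response, lambdas, k = 10, seed = 1L,
                           contiguous = FALSE, predictors = NULL) {
  predictors <- predictors %||% predictor_cols(data, response)
  ids <- fold_ids(nrow(data), k, seed, contiguous)
  r2 <- matrix(NA_real_, nrow = length(lambdas), ncol = k)
  for (fold in seq_len(k)) {
    tr <- data[ids != fold, , drop = FALSE]
    te <- data[ids == fold, , drop = FALSE]
    xs <- withCallingHandlers(
      fit_scaler(tr, predictors),
      warning = function(w) invokeRestart("muffleWarning")
    )
    y_mu <- mean(tr[[response]])
    y_sd <- sd(tr[[response]])
    if (y_sd == 0) y_sd <- 1
    xtr <- as.matrix(apply_scaler(tr, xs)[, xs$cols, drop = FALSE])
    xte <- as.matrix(apply_scaler(te, xs)[, xs$cols, drop = FALSE])
    ytr <- (tr[[response]] - y_mu) / y_sd
    sv <- svd(xtr)
    uty <- drop(crossprod(sv$u, ytr))
    for (li in seq_along(lambdas)) {
      shrink <- sv$d / (sv$d^2 + lambdas[li])
      beta <- drop(sv$v %*% (shrink * uty))
      pred <- drop(xte %*% beta) * y_sd + y_mu
      r2[li, fold] <- r_squared(te[[response]], pred)
    }
  }
  tibble::tibble(lambda = lambdas, r2 = rowMeans(r2))
}

#' Select the ridge shrinkage parameter on an integer grid
#'
#' For each candidate `lambda` (by default every integer 1-100) the mean
#' 10-fold cross-validated R^2 is computed on every dataset; the per-lambda
#' values are averaged across datasets, smoothed with a centred moving
#' average (width 9), and the `lambda` maximising the smoothed curve is
#' returned (ties broken towards the smaller, more parsimonious value).
#'
#' @param datasets A data frame, or a list of data frames, each containing
#'   the predictors and the response.
#' @param response Name of the response column.
#' @param lambda_grid Candidate shrinkage values (default `1:100`).
#' @param k Folds for the internal CV (default 10).
#' @param seed Integer seed for fold assignment.
#' @param smooth_width Width of the centred moving-average smoother
#'   (default 9).
#' @param predictors Optional predictor names.
#' @return List with `lambda` (the selected value) and `curve` (tibble
#'   `lambda`, `r2_raw`, `r2_smooth`).
#' @export
select_shrinkage <- function(datasets, response, lambda_grid = 1:100,
                             k = 10, seed = 1L, smooth_width = 9,
                             predictors = NULL) {
  if (length(lambda_grid) == 0) abort("empty lambda grid")
  if (is.data.frame(datasets)) datasets <- list(datasets)
  curves <- purrr::map(seq_along(datasets), function(i) {
    ridge_cv_curve(datasets[[i]], response, lambda_grid,
      k = k,
      seed = seed + i, predictors = predictors
    )$r2
  })
  raw <- rowMeans(do.call(cbind, curves))
  smooth <- moving_average(raw, smooth_width)
  best <- lambda_grid[which.max(smooth)] # which.max: first index on ties
  list(
    lambda = best,
    curve = tibble::tibble(
      lambda = lambda_grid, r2_raw = raw, r2_smooth = smooth
    )
  )
}
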