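#' Random-forest regression with out-of-bag evaluation
#'
#' Fits a bagged regression forest (100 trees by default, `mtry` one third
#' of the variables, i.e. 12 for the 36-variable feature set) via the
#' `randomForest` package.  Each tree is grown on a bootstrap sample of the
#' training rows; the roughly `1 - (1 - 1/n)^n ~ 37%` of rows left out of a
#' tree's bootstrap form its out-of-bag (OOB) set, used for unbiased
#' evaluation and permutation importance.  The response is used on its raw
#' scale (forests are invariant to monotone transformations).
#'
#' @param data Data frame with predictors and the response.
#' @param response Name of the response column.
#' @param n_trees Number of trees (default 100).
#' @param mtry Variables tried at each split; default `floor(p / 3)`.
#' @param seed Integer seed; fixes bootstrap and split randomisation.
#' @param predictors Optional predictor names.
#' @return Object of class `cyclemg_forest` wrapping the fitted forest,
#'   with OOB predictions, the per-tree in-bag matrix and permutation
#'   importances.  Supports `predict()`, [tidy()] (importances) and
#'   [glance()].
#' @export
#' @examples
#' d <- data.frame(x1 = runif(50), x2 = runif(50))
#' d$y <- sin(3 * d$x1) + rnorm(50, sd = 0.1)
#' fit <- forest_fit(d, "y", seed = 1)
#' glance(fit)
forest_fit <- function(data, response, n_trees = 100, mtry = NULL,
                       seed = 1L, predictors = NULL) {
  if (nrow(data) < 10) abort("need at least 10 rows to grow a forest")
  predictors <- predictors %||% predictor_cols(data, response)
  p <- length(predictors)
  mtry <- mtry %||% max(1L, floor(p / 3))
  if (mtry > p) abort("mtry cannot exceed the number of predictors")
  x <- as.data.frame(data[, predictors, drop = FALSE])
  y <- data[[response]]
  rf <- withr::with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    importance = TRUE, keep.inbag = TRUE
  ))
  structure(
    list(
      rf = rf, response = response, predictors = predictors,
      n_trees = n_trees, mtry = mtry, seed = seed, n = nrow(data),
      y = y
    ),
    class = "cyclemg_forest"
  )
}

#' @export
predict.cyclemg_forest <- function(object, newdata, ...) {
  unname(predict(object$rf, newdata = as.data.frame(
    newdata[, object$predictors, drop = FALSE]
  )))
}

#' @export
print.cyclemg_forest <- function(x, ...) {
  cat(sprintf(
    "<cyclemg_forest> %s ~ %d predictors, %d trees, mtry = %d, OOB R^2 = %.3f\n",
    x$response, length(x$predictors), x$n_trees, x$mtry,
    r_squared(x$y, oob_predictions(x))
  ))
  invisible(x)
}

#' Out-of-bag predictions of a fitted forest
#'
#' Per-row prediction averaged over the trees whose bootstrap sample did
#' not contain that row.  Rows that landed in every bootstrap sample have
#' no OOB trees and are `NA` (excluded, with a warning, by
#' [forest_oob_r2()]).
#'
#' @param model A `cyclemg_forest`.
#' @return Numeric vector of length `n`.
#' @export
oob_predictions <- function(model) {
  stopifnot(inherits(model, "cyclemg_forest"))
  unname(model$rf$predicted)
}

#' Per-tree out-of-bag fraction
#'
#' @param model A `cyclemg_forest`.
#' @return Numeric vector (one value per tree) of the fraction of training
#'   rows absent from that tree's bootstrap sample; about `1 - (1 - 1/n)^n`
#'   (roughly a third) for bootstrap samples of size `n`.
#' @export
oob_fraction <- function(model) {
  stopifnot(inherits(model, "cyclemg_forest"))
  colMeans(model$rf$inbag == 0)
}

#' Seed-averaged out-of-bag R^2
#'
#' Fits the forest under several random seeds and reports the coefficient
#' of determination of the OOB predictions for each, plus their mean --
#' averaging over seeds reduces the Monte-Carlo variance of the estimate.
#'
#' @inheritParams forest_fit
#' @param n_seeds Number of seeds (default 10); seeds are
#'   `seed + 0:(n_seeds-1)`.
#' @return List with `mean_r2`, `per_seed` (tibble `seed`, `r2`) and
#'   `models` (list of fitted forests).
#' @export
forest_oob_r2 <- function(data, response, n_trees = 100, mtry = NULL,
                          seed = 1L, n_seeds = 10, predictors = NULL) {
  seeds <- seed + seq_len(n_seeds) - 1L
  models <- purrr::map(seeds, function(s) {
    forest_fit(data, response,
      n_trees = n_trees, mtry = mtry, seed = s,
      predictors = predictors
    )
  })
  r2s <- purrr::map_dbl(models, function(m) {
    pred <- oob_predictions(m)
    ok <- !is.na(pred)
    if (any(!ok)) {
      warn(sprintf("%d row(s) with no OOB trees excluded from R^2", sum(!ok)))
    }
    r_squared(m$y[ok], pred[ok])
  })
  list(
    mean_r2 = mean(r2s),
    per_seed = tibble::tibble(seed = seeds, r2 = r2s),
    models = models
  )
}

#' Permutation variable importance on out-of-bag data
#'
#' For each variable, the increase in out-of-bag mean-squared error when
#' that variable's values are randomly permuted (averaged over trees);
#' variables whose scrambling degrades prediction the most are the most
#' important.  Optionally averaged over several seeds and normalised to sum
#' to one, so the values are comparable with the equal-importance reference
#' `1/p`.
#'
#' @inheritParams forest_oob_r2
#' @param normalize If `TRUE`, divide by the total so importances sum to 1.
#' @return Tibble with `variable` and `importance`, in predictor order.
#' @export
permutation_importance <- function(data, response, n_trees = 100, mtry = NULL,
                                   seed = 1L, n_seeds = 1, normalize = FALSE,
                                   predictors = NULL) {
  seeds <- seed + seq_len(n_seeds) - 1L
  imps <- purrr::map(seeds, function(s) {
    m <- forest_fit(data, response,
      n_trees = n_trees, mtry = mtry, seed = s,
      predictors = predictors
    )
    randomForest::importance(m$rf, type = 1, scale = FALSE)[, 1]
  })
  imp <- rowMeans(do.call(cbind, imps))
  if (normalize) {
    tot <- sum(imp)
    if (tot != 0) imp <- imp / tot
  }
  tibble::tibble(variable = names(imp), importance = unname(imp))
}

#' @rdname forest_fit
#' @param x A fitted `cyclemg_forest`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cyclemg_forest <- function(x, ...) {
  imp <- randomForest::importance(x$rf, type = 1, scale = FALSE)[, 1]
  tibble::tibble(variable = names(imp), importance = unname(imp))
}

#' @rdname forest_fit
#' @exportS3Method generics::glance
glance.cyclemg_forest <- function(x, ...) {
  pred <- oob_predictions(x)
  ok <- !is.na(pred)
  tibble::tibble(
    n_trees = x$n_trees, mtry = x$mtry, n = x$n,
    oob_r2 = r_squared(x$y[ok], pred[ok]), response = x$response
  )
}
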