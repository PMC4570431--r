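make_xy <- function(n = 50, p = 5, seed = 1, sigma = 0.1) {
  withr::with_seed(seed, {
    d <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(d) <- paste0("x", seq_len(p))
    d$y <- d$x1 + 0.5 * d$x2 + rnorm(n, sd = sigma)
    tibble::as_tibble(d)
  })
}

test_that("scaler standardises training data and survives a round trip", {
  d <- make_xy(40)
  sc <- fit_scaler(d, paste0("x", 1:5))
  z <- apply_scaler(d, sc)
  expect_true(all(abs(colMeans(as.matrix(z[sc$cols]))) < 1e-9))
  expect_true(all(abs(apply(as.matrix(z[sc$cols]), 2, sd) - 1) < 1e-9))
  back <- apply_scaler(z, sc, inverse = TRUE)
  expect_equal(as.data.frame(back[sc$cols]), as.data.frame(d[sc$cols]),
    tolerance = 1e-12
  )

  d$flat <- 1
  expect_warning(sc2 <- fit_scaler(d, c("x1", "flat")), "zero-variance")
  expect_equal(sc2$cols, "x1")
})

test_that("ridge at lambda = 0 equals ordinary least squares", {
  d <- make_xy(60, seed = 2)
  fit <- ridge_fit(d, "y", lambda = 0)
  # oracle: lm on z-scored data, no intercept
  z <- scale(as.matrix(d[paste0("x", 1:5)]))
  yz <- scale(d$y)[, 1]
  ols <- unname(stats::lm.fit(z, yz)$coefficients)
  expect_equal(unname(fit$beta), ols, tolerance = 1e-9)
})

test_that("ridge matches the augmented least-squares oracle at the study lambdas", {
  for (lambda in c(18, 32, 100)) {
    d <- make_xy(50, p = 36, seed = 3 + lambda, sigma = 0.5)
    fit <- ridge_fit(d, "y", lambda = lambda)
    z <- scale(as.matrix(d[paste0("x", 1:36)]))
    yz <- scale(d$y)[, 1]
    expect_equal(
      unname(fit$beta),
      unname(oracle_ridge_augmented(z, yz, lambda)),
      tolerance = 1e-9
    )
  }
  # the printed 5x2 toy case
  d2 <- tibble::tibble(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 1, 4, 3, 6), y = c(1.2, 1.9, 3.1, 4.2, 5.3))
  f2 <- ridge_fit(d2, "y", lambda = 32)
  z2 <- scale(as.matrix(d2[c("x1", "x2")]))
  expect_equal(
    unname(f2$beta),
    unname(oracle_ridge_augmented(z2, scale(d2$y)[, 1], 32)),
    tolerance = 1e-9
  )
})

test_that("extreme shrinkage collapses the weights and norms shrink monotonically", {
  d <- make_xy(50, seed = 5)
  big <- ridge_fit(d, "y", lambda = 1e9)
  expect_lt(sqrt(sum(big$beta^2)), 1e-3)

  norms <- sapply(c(0, 1, 10, 100, 1000), function(l) {
    sqrt(sum(ridge_fit(d, "y", lambda = l)$beta^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("collinear predictors at lambda = 0 raise the advisory error", {
  d <- make_xy(30, seed = 6)
  d$x6 <- d$x1 # exact copy
  expect_error(ridge_fit(d, "y", lambda = 0), "lambda > 0")
  expect_silent(ridge_fit(d, "y", lambda = 1))
})

test_that("ridge predictions return to response units", {
  d <- make_xy(80, seed = 7)
  d$y <- 100 + 5 * d$x1
  fit <- ridge_fit(d, "y", lambda = 1)
  pred <- predict(fit, d)
  expect_equal(pred, d$y, tolerance = 0.05)
  expect_equal(tidy(fit)$variable, paste0("x", 1:5))
  expect_equal(glance(fit)$lambda, 1)
})

test_that("shrinkage selection prefers no shrinkage on noise-free linear data", {
  d <- make_xy(120, seed = 8, sigma = 0)
  sel <- select_shrinkage(d, "y", lambda_grid = 1:100, k = 10, seed = 1)
  expect_equal(sel$lambda, 1)
  expect_true(all(diff(sel$curve$r2_smooth[1:50]) <= 1e-12))

  sel2 <- select_shrinkage(list(d, d), "y", lambda_grid = 1:100, k = 10, seed = 1)
  expect_equal(sel2$lambda, sel$lambda)

  one <- select_shrinkage(d, "y", lambda_grid = 42, k = 5, seed = 1)
  expect_equal(one$lambda, 42)
  expect_error(select_shrinkage(d, "y", lambda_grid = integer(0)), "empty")
})

test_that("a forest on constant y predicts that constant; same seed reproduces", {
  d <- make_xy(40, seed = 9)
  d$y <- 7
  # randomForest advises against regression on <= 5 unique y values; the
  # degenerate case is intentional here
  fit <- suppressWarnings(forest_fit(d, "y", seed = 1))
  expect_true(all(abs(predict(fit, d) - 7) < 1e-9))

  d2 <- make_xy(100, seed = 10)
  a <- forest_fit(d2, "y", seed = 5)
  b <- forest_fit(d2, "y", seed = 5)
  expect_identical(oob_predictions(a), oob_predictions(b))
  c_ <- forest_fit(d2, "y", seed = 6)
  expect_false(identical(oob_predictions(a), oob_predictions(c_)))
})

test_that("per-tree OOB fraction matches the bootstrap expectation", {
  d <- make_xy(1000, seed = 11)
  fit <- forest_fit(d, "y", seed = 2)
  fr <- oob_fraction(fit)
  expected <- (1 - 1 / 1000)^1000 # ~ 1/e ~ 0.368, "about one third"
  expect_lt(abs(mean(fr) - expected), 0.03)
  expect_equal(length(fr), 100)
})

test_that("forest defaults follow the one-third mtry rule", {
  d <- make_xy(60, p = 36, seed = 12)
  fit <- forest_fit(d, "y", seed = 1)
  expect_equal(fit$mtry, 12)
  expect_equal(fit$n_trees, 100)
  expect_error(forest_fit(d, "y", mtry = 40, seed = 1), "mtry")
})

test_that("forest recovers a monotone single-variable signal out of bag", {
  withr::with_seed(13, {
    d <- as.data.frame(matrix(rnorm(500 * 10), 500, 10))
    names(d) <- paste0("x", 1:10)
    d$y <- 1 / (1 + exp(-3 * d$x1)) + rnorm(500, sd = 0.05)
  })
  res <- forest_oob_r2(d, "y", seed = 1, n_seeds = 3)
  expect_gte(res$mean_r2, 0.8)
  expect_equal(nrow(res$per_seed), 3)
  expect_lt(sd(res$per_seed$r2), 0.05) # seeds agree closely
})

test_that("permutation importance finds the planted variable and ignores noise", {
  withr::with_seed(14, {
    d <- as.data.frame(matrix(rnorm(300 * 8), 300, 8))
    names(d) <- paste0("x", 1:8)
    d$y <- 2 * d$x3 + rnorm(300, sd = 0.1)
  })
  imp <- permutation_importance(d, "y", seed = 3, n_seeds = 3)
  expect_equal(imp$variable[which.max(imp$importance)], "x3")
  # pure-noise columns sit near zero
  noise_imp <- imp$importance[imp$variable != "x3"]
  expect_lt(max(abs(noise_imp)), 0.1 * max(imp$importance))

  impn <- permutation_importance(d, "y", seed = 3, n_seeds = 2, normalize = TRUE)
  expect_equal(sum(impn$importance), 1, tolerance = 1e-9)
})
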