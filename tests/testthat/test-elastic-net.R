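test_that("MSE follows its definition", {
  expect_equal(mse(c(1, 2), c(2, 4)), 2.5)
  expect_equal(mse(1:5, 1:5), 0)
  set.seed(91)
  y <- stats::rnorm(10); yh <- stats::rnorm(10); cc <- stats::runif(1, -5, 5)
  expect_equal(mse(y + cc, yh + cc), mse(y, yh), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "length mismatch")
})

test_that("unpenalised fit equals ordinary least squares", {
  set.seed(92)
  X <- matrix(stats::rnorm(15), 5, 3)
  y <- stats::rnorm(5)
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  for (std in c(TRUE, FALSE)) {
    fit <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0, standardize = std)
    expect_equal(unname(fit$coefficients), ols[-1], tolerance = 1e-6)
    expect_equal(fit$intercept, ols[1], tolerance = 1e-6)
  }
  # over-determined instance against the pseudo-inverse solution
  X2 <- matrix(stats::rnorm(40 * 6), 40, 6)
  y2 <- stats::rnorm(40)
  b2 <- drop(solve(crossprod(cbind(1, X2)), crossprod(cbind(1, X2), y2)))
  fit2 <- fit_elastic_net(X2, y2, alpha = 1, lambda = 0)
  expect_equal(unname(fit2$coefficients), b2[-1], tolerance = 1e-6)
})

test_that("the penalty-dominated limit is the zero model", {
  set.seed(93)
  X <- matrix(stats::rnorm(60), 20, 3)
  y <- stats::rnorm(20, 4)
  fit <- fit_elastic_net(X, y, alpha = 0.7, lambda = 1e6)
  expect_equal(unname(fit$coefficients), c(0, 0, 0))
  expect_equal(fit$intercept, mean(y))
})

test_that("1-D lasso equals the soft-thresholded covariance", {
  set.seed(94)
  n <- 30
  x <- as.matrix(scale(stats::rnorm(n)))  # centred, unit sample sd
  y <- stats::rnorm(n, 2 * x)
  for (lambda in c(0.05, 0.5, 5)) {
    fit <- fit_elastic_net(x, y, alpha = 1, lambda = lambda, standardize = FALSE)
    rho <- sum(x * (y - mean(y))) / n
    xx <- sum(x^2) / n
    want <- sign(rho) * max(abs(rho) - lambda, 0) / xx
    expect_equal(unname(fit$coefficients), want, tolerance = 1e-8)
  }
})

test_that("coordinate descent agrees with the glmnet reference", {
  set.seed(95)
  n <- 20; p <- 10
  X <- scale(matrix(stats::rnorm(n * p), n, p))
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + stats::rnorm(n, 0, 0.5)
  # glmnet standardises the response internally, which rescales its ridge
  # term by 1/sd(y); the conventions coincide at unit population variance
  y <- y / sqrt(mean((y - mean(y))^2))
  for (case in list(c(1, 0.1), c(0.5, 0.2), c(0.2, 0.05))) {
    alpha <- case[1]; lambda <- case[2]
    ours <- fit_elastic_net(X, y, alpha, lambda, standardize = FALSE, tol = 1e-10)
    ref <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                          standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(ours$coefficients), as.numeric(ref$beta), tolerance = 1e-5)
    expect_equal(ours$intercept, as.numeric(ref$a0), tolerance = 1e-5)
  }
})

test_that("the objective decreases monotonically across sweeps", {
  set.seed(96)
  X <- matrix(stats::rnorm(25 * 60), 25, 60)  # p > n, slow small-lambda case
  y <- stats::rnorm(25)
  for (pars in list(c(1, 1e-4), c(0.3, 1e-3), c(0.9, 0.05))) {
    fit <- fit_elastic_net(X, y, pars[1], pars[2])
    expect_gte(length(fit$objective), 1L)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("the lasso active set shrinks as lambda grows", {
  set.seed(97)
  for (rep in 1:5) {
    X <- matrix(stats::rnorm(40 * 15), 40, 15)
    y <- drop(X[, 1:4] %*% stats::rnorm(4)) + stats::rnorm(40, 0, 0.3)
    lambdas <- exp(seq(log(1e-3), log(2), length.out = 12))
    nz <- vapply(lambdas, function(l) {
      sum(fit_elastic_net(X, y, 1, l)$coefficients != 0)
    }, numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
})

test_that("LOOCV tuning never lets a sample into its own training fold", {
  set.seed(98)
  n <- 12; p <- 8
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- drop(X[, 1] * 2) + stats::rnorm(n, 0, 0.3)
  base <- tune_and_evaluate(X, y, alpha_grid = c(0.5, 1), nlambda = 10)
  for (i in c(1, 5, 12)) {
    y_poison <- y
    y_poison[i] <- y[i] + 50  # corrupt only the held-out response
    poisoned <- tune_and_evaluate(X, y_poison, alpha_grid = c(0.5, 1), nlambda = 10)
    # fold i trains without row i, so its predictions over the whole grid
    # cannot react to the corruption (the winning grid point may move)
    expect_equal(poisoned$cv_predictions[i, , ], base$cv_predictions[i, , ],
                 tolerance = 1e-10)
  }
})

test_that("tuning degenerates gracefully and reports consistent results", {
  set.seed(99)
  n <- 10
  X <- matrix(stats::rnorm(n * 5), n, 5)
  y <- drop(X[, 1]) + stats::rnorm(n, 0, 0.2)
  single <- tune_and_evaluate(X, y, alpha_grid = 0.7, nlambda = 1)
  expect_equal(single$alpha, 0.7)
  expect_equal(dim(single$cv_mse_grid), c(1L, 1L))
  # reported MSE equals the definition applied to the stored pairs
  expect_equal(single$cv_mse, mse(single$pairs$observed, single$pairs$predicted))
  expect_error(tune_and_evaluate(X, rep(1, n)), "zero variance")
  expect_error(tune_and_evaluate(X[1:2, ], y[1:2]), "n >= 3")
})

test_that("platform comparison is symmetric for identical platforms and validates products", {
  bnd <- shared_bundle()
  std <- standardize_sensory(bnd$sensory)
  res <- compare_platforms_level3(bnd$table_a, bnd$table_a, std, "umami.fl",
                                  alpha_grid = c(0.5, 1), nlambda = 15)
  expect_equal(res$mse_a, res$mse_b)

  crippled <- bnd$table_a
  keep <- crippled$samples$product_id != "P05" | crippled$samples$role != "product"
  crippled$samples <- crippled$samples[keep, ]
  crippled$intensities <- crippled$intensities[, keep]
  expect_error(compare_platforms_level3(crippled, bnd$table_b, std, "umami.fl"),
               "P05")
})

test_that("the platform uniquely carrying the signal predicts the attribute better", {
  wins <- 0L
  for (s in 1:20) {
    bnd <- default_study_fixture(
      seed = 400 + s, n_features_a = 30, n_features_b = 30, n_common = 15,
      n_annotated_common = 5, n_annotated_unique_a = 3, n_annotated_unique_b = 3,
      design_effects = list(),
      sensory_effects = list(aroma = list(n_common = 0, n_unique_a = 0,
                                          n_unique_b = 6, noise_sd = 3)))
    std <- standardize_sensory(bnd$sensory)
    res <- compare_platforms_level3(bnd$table_a, bnd$table_b, std, "aroma",
                                    alpha_grid = c(0.5, 1), nlambda = 15)
    if (res$mse_b < res$mse_a) wins <- wins + 1L
  }
  expect_gte(wins, 18L)  # >= 90% of 20 seeded runs
})
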