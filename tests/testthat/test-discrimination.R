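test_that("balanced error rate follows its definition and symmetries", {
  expect_equal(ber(4, 0, 10, 0), 0)
  expect_equal(ber(0, 4, 0, 10), 1)
  expect_equal(ber(3, 1, 10, 2), 1 - 0.5 * (0.75 + 10 / 12), tolerance = 1e-12)
  expect_error(ber(0, 0, 5, 1), "at least one sample")
  # class symmetry
  set.seed(71)
  for (i in 1:20) {
    cm <- sample(0:20, 4, replace = TRUE) + c(1, 0, 1, 0)
    expect_equal(ber(cm[1], cm[2], cm[3], cm[4]), ber(cm[3], cm[4], cm[1], cm[2]))
  }
})

test_that("point-biserial equals Pearson correlation with dummy coding", {
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(point_biserial(c(5, 7, 5, 7), c(0, 1, 1, 0)), 0)
  set.seed(72)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    v <- stats::rnorm(n)
    g <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    expect_equal(point_biserial(v, g), stats::cor(v, g), tolerance = 1e-12)
    expect_equal(point_biserial(v, 1 - g), -point_biserial(v, g), tolerance = 1e-12)
  }
  expect_true(is.na(point_biserial(rep(2, 6), c(0, 0, 0, 1, 1, 1))))
})

test_that("design contrasts reproduce the study group sizes", {
  d <- soup_design()
  o31 <- contrast_from_design(d, "yeast_product", "Maxagusto O-31")
  expect_equal(o31$n_positive, 7L)
  expect_equal(o31$n_negative, 20L)
  oil <- contrast_from_design(d, "oil_type", "Olive")
  expect_equal(oil$n_positive, 19L)
  expect_equal(oil$n_negative, 8L)
  expect_error(contrast_from_design(d, "oil_type", "Sunflower"), "absent")
  expect_error(contrast_from_design(d, "nope", "x"), "not in design")
  all_level <- design_table(data.frame(product_id = c("P1", "P2"), f = c("a", "a")))
  expect_error(contrast_from_design(all_level, "f", "a"), "empty negative class")
})

test_that("PLS-DA separates well-separated clouds and matches the 1-predictor closed form", {
  set.seed(73)
  n <- 40; p <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1:10] <- X[, 1:10] + 5 * y  # delta mu = 5 sigma on 10 informative features
  fx <- level2_fixture(X, y)
  model <- fit_plsda(fx$table, fx$contrast, n_components = 2)
  d <- metabocompare:::level2_matrix(fx$table, fx$contrast)
  expect_equal(unname(predict(model, d$X, type = "class")), y)  # training BER 0

  # single predictor, single component: b is the OLS slope on centred data
  X1 <- matrix(stats::rnorm(20), 20, 1)
  y1 <- rep(c(0, 1), 10)
  fx1 <- level2_fixture(X1, y1)
  m1 <- fit_plsda(fx1$table, fx1$contrast, n_components = 1)
  d1 <- metabocompare:::level2_matrix(fx1$table, fx1$contrast)
  xc <- d1$X - mean(d1$X); yc <- y1 - mean(y1)
  expect_equal(unname(m1$b), sum(xc * yc) / sum(xc^2), tolerance = 1e-10)

  # scores are mutually orthogonal
  expect_lt(abs(crossprod(model$scores)[1, 2]) /
              sqrt(prod(diag(crossprod(model$scores)))), 1e-8)

  expect_error(fit_plsda(fx1$table, fx1$contrast, n_components = 25), "exceeds")
})

test_that("PLS-DA component agrees with the mixOmics reference implementation", {
  set.seed(74)
  n <- 24; p <- 15
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1:3] <- X[, 1:3] + 1.5 * y
  fx <- level2_fixture(X, y)
  model <- fit_plsda(fx$table, fx$contrast, n_components = 2)
  d <- metabocompare:::level2_matrix(fx$table, fx$contrast)
  ref <- mixOmics::plsda(d$X, factor(y), ncomp = 2, scale = FALSE)
  # component-1 latent scores match up to sign
  expect_gt(abs(stats::cor(model$scores[, 1], ref$variates$X[, 1])), 0.999)
})

test_that("model is invariant to duplicating every sample", {
  set.seed(75)
  X <- matrix(stats::rnorm(18 * 6), 18, 6)
  y <- rep(c(0, 1), 9)
  fx1 <- level2_fixture(X, y)
  m1 <- fit_plsda(fx1$table, fx1$contrast, 2)
  fx2 <- level2_fixture(rbind(X, X), c(y, y))
  m2 <- fit_plsda(fx2$table, fx2$contrast, 2)
  expect_equal(m1$b, m2$b, tolerance = 1e-9)
})

test_that("cross-validation is stratified, deterministic and honest", {
  set.seed(76)
  n <- 40; p <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1:5] <- X[, 1:5] + 4 * y
  fx <- level2_fixture(X, y)
  r1 <- cv_plsda(fx$table, fx$contrast, n_components = 2, folds = 5, seed = 10)
  r2 <- cv_plsda(fx$table, fx$contrast, n_components = 2, folds = 5, seed = 10)
  expect_identical(r1, r2)
  expect_lte(r1$ber, 0.1)
  expect_equal(sum(r1$confusion[c("tp", "fn")]), sum(y == 1))
  expect_equal(sum(r1$confusion[c("tn", "fp")]), sum(y == 0))
  # BER recomputed from the pooled confusion equals the reported BER
  expect_equal(r1$ber, ber(r1$confusion[["tp"]], r1$confusion[["fn"]],
                           r1$confusion[["tn"]], r1$confusion[["fp"]]))

  expect_error(cv_plsda(fx$table, fx$contrast, folds = 41), "more folds than samples")
  y_small <- c(rep(0, 37), rep(1, 3))
  fx_small <- level2_fixture(X, y_small)
  expect_error(cv_plsda(fx_small$table, fx_small$contrast, folds = 5), "stratified")
})

test_that("permutation null CV BER is centred at one half", {
  set.seed(77)
  n <- 60; p <- 40
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  bers <- vapply(1:20, function(s) {
    yp <- sample(y)
    fx <- level2_fixture(X, yp)
    cv_plsda(fx$table, fx$contrast, n_components = 2, folds = 5, seed = s)$ber
  }, numeric(1))
  expect_gt(mean(bers), 0.4)
  expect_lt(mean(bers), 0.6)
})

test_that("selectivity ratio ranks the informative feature first", {
  set.seed(78)
  n <- 30; p <- 25
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 7] <- X[, 7] + 4 * y  # the single informative feature
  fx <- level2_fixture(X, y)
  model <- fit_plsda(fx$table, fx$contrast, 2)
  sr <- selectivity_ratio(model, fx$table)
  expect_equal(which.max(sr), 7L, ignore_attr = TRUE)
  expect_gt(sr[7], 1)

  # pure-noise features carry low ratios
  expect_lt(stats::median(sr[-7]), 0.5)

  # a single-feature table is reconstructed exactly: ratio flagged infinite
  X1 <- matrix(stats::rnorm(20), 20, 1)
  fx1 <- level2_fixture(X1, rep(c(0, 1), 10))
  m1 <- fit_plsda(fx1$table, fx1$contrast, 1)
  expect_true(is.infinite(selectivity_ratio(m1, fx1$table)))

  # invariance to rescaling the whole data matrix
  fx_scaled <- fx
  fx_scaled$table$intensities <- fx$table$intensities * 7
  m_s <- fit_plsda(fx_scaled$table, fx$contrast, 2)
  sr_s <- selectivity_ratio(m_s, fx_scaled$table)
  expect_equal(unname(sr_s), unname(sr), tolerance = 1e-8)
})

test_that("pure-noise response yields a near-zero first-component response fit", {
  set.seed(79)
  n <- 50; p <- 200
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  fx <- level2_fixture(X, y)
  model <- fit_plsda(fx$table, fx$contrast, 1)
  d <- metabocompare:::level2_matrix(fx$table, fx$contrast)
  pred <- predict(model, d$X, type = "response")
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  # with p >> n some apparent fit is unavoidable; compare against the
  # permutation spread of the same statistic
  null_r2 <- vapply(1:20, function(i) {
    yp <- sample(y)
    fxp <- level2_fixture(X, yp)
    mp <- fit_plsda(fxp$table, fxp$contrast, 1)
    dp <- metabocompare:::level2_matrix(fxp$table, fxp$contrast)
    pp <- predict(mp, dp$X, type = "response")
    1 - sum((yp - pp)^2) / sum((yp - mean(yp))^2)
  }, numeric(1))
  expect_lte(r2, max(null_r2) + 0.1)
})
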