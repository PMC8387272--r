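#' Mean squared prediction error
#'
#' \deqn{MSE = \sum_i (y_i - \hat y_i)^2 / n.} MSE is not a relative measure:
#' models for the same response can be compared by it, models for different
#' responses cannot.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Non-negative number.
#' @examples
#' mse(c(1, 2), c(2, 4))  # 2.5
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(observed) < 1L) stop("need at least one pair", call. = FALSE)
  mean((observed - predicted)^2)
}

#' Fit an elastic-net regression model
#'
#' Minimises \deqn{\frac{1}{2n}\lVert y - X\beta\rVert^2 +
#' \lambda\big(\alpha\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\big)}
#' by cyclic coordinate descent with soft-thresholding on centred (and, by
#' default, unit-scaled) predictors. `alpha = 1` is the lasso, `alpha = 0`
#' ridge. Coefficients are returned on the original predictor scale with the
#' matching intercept. The per-sweep objective values are stored; the descent
#' is monotone by construction.
#'
#' @param x numeric predictor matrix (samples x features), e.g. square-root
#'   transformed metabolite intensities per product.
#' @param y numeric response (e.g. a standardised sensory attribute per
#'   product).
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda regularisation strength, >= 0.
#' @param standardize scale columns to unit (n-1) standard deviation before
#'   penalisation so the penalty treats features of different magnitude
#'   fairly (default TRUE). Constant columns get coefficient 0.
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep (default 1e-7).
#' @param max_sweeps sweep budget (default 1e5).
#' @param beta_init optional warm-start coefficients on the standardised
#'   scale.
#' @return An object of class `elastic_net` with `intercept`, `coefficients`
#'   (original scale, named), `alpha`, `lambda`, preprocessing vectors,
#'   `objective` (per-sweep path) and `converged`.
#' @export
fit_elastic_net <- function(x, y, alpha, lambda, standardize = TRUE,
                            tol = 1e-7, max_sweeps = 1e5, beta_init = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree on the number of samples", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)) || anyNA(y) || any(!is.finite(y))) {
    stop("non-finite values in x or y", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0", call. = FALSE)

  centers <- colMeans(x)
  scales <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scales[scales == 0 | is.na(scales)] <- 1  # constant column: leave unscaled, beta ends 0
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  ybar <- mean(y)
  if (is.null(beta_init)) beta_init <- numeric(ncol(x))
  fit <- enet_cd(xs, y - ybar, alpha, lambda, as.numeric(beta_init),
                 tol, as.integer(max_sweeps))
  beta_std <- fit$beta
  beta <- beta_std / scales
  names(beta) <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  structure(list(intercept = ybar - sum(centers * beta),
                 coefficients = beta, beta_std = beta_std,
                 alpha = alpha, lambda = lambda,
                 centers = centers, scales = scales, standardize = standardize,
                 objective = fit$objective, converged = fit$converged,
                 sweeps = fit$sweeps),
            class = "elastic_net")
}

#' @export
print.elastic_net <- function(x, ...) {
  cat(sprintf("<elastic_net: alpha %.2f, lambda %.4g, %d/%d non-zero coefficients%s>\n",
              x$alpha, x$lambda, sum(x$coefficients != 0), length(x$coefficients),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.elastic_net <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a fitted elastic-net model
#' @param object an `elastic_net` model.
#' @param newdata matrix of samples x features on the training scale.
#' @param ... unused.
#' @export
predict.elastic_net <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has wrong number of features", call. = FALSE)
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

# lambda path: geometric grid over `decades` decades down from lambda_max,
# the smallest lambda that zeroes every coefficient on this (centred,
# scaled) design. For small alpha the l1 part vanishes; alpha is floored to
# keep lambda_max finite, the conventional fix.
lambda_path <- function(xs, yc, alpha, nlambda = 50, decades = 4) {
  lmax <- max(abs(crossprod(xs, yc))) / (nrow(xs) * max(alpha, 1e-3))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

#' Tune an elastic net by leave-one-out cross-validation
#'
#' The mixing parameter alpha and the regularisation strength lambda are
#' optimised simultaneously: for every alpha in `alpha_grid` and every lambda
#' on a geometric path (`nlambda` points over `lambda_decades` decades down
#' from lambda_max), leave-one-out predictions are computed and scored by
#' [mse()]. Each fold standardises on its own training rows and uses its own
#' training-data lambda path (aligned across folds by the fixed
#' lambda/lambda_max ratios), so the held-out sample never influences
#' training. Ties are broken towards the larger lambda, then the larger
#' alpha — the sparser model.
#'
#' @inheritParams fit_elastic_net
#' @param alpha_grid candidate mixing parameters (default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9, 1)`).
#' @param nlambda number of lambda path points (default 50).
#' @param lambda_decades decades spanned below lambda_max (default 4).
#' @return An object of class `prediction_result`: `alpha`, `lambda`
#'   (full-data path value at the winning index), `cv_mse` (winning score),
#'   `cv_mse_grid` (alpha x lambda matrix), `cv_predictions` (out-of-fold
#'   prediction array, samples x alpha x lambda), `pairs` (per-sample observed and
#'   out-of-fold predicted values for the winner), `model` (final fit on all
#'   data), `selected_features` (non-zero coefficients of the final model).
#' @export
tune_and_evaluate <- function(x, y, alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                              nlambda = 50, lambda_decades = 4,
                              standardize = TRUE, tol = 1e-7, max_sweeps = 1e5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out tuning needs n >= 3", call. = FALSE)
  if (length(alpha_grid) < 1L || nlambda < 1L) stop("empty tuning grid", call. = FALSE)
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)

  ratios <- exp(seq(0, -lambda_decades * log(10), length.out = nlambda))
  preds <- array(NA_real_, dim = c(n, length(alpha_grid), nlambda))
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    centers <- colMeans(xtr)
    scales <- if (standardize) apply(xtr, 2, stats::sd) else rep(1, ncol(x))
    scales[scales == 0 | is.na(scales)] <- 1
    xs <- sweep(sweep(xtr, 2, centers), 2, scales, "/")
    ybar <- mean(ytr)
    yc <- ytr - ybar
    xnew <- (x[i, ] - centers) / scales
    for (a in seq_along(alpha_grid)) {
      lmax <- max(abs(crossprod(xs, yc))) / ((n - 1) * max(alpha_grid[a], 1e-3))
      if (lmax <= 0) lmax <- 1e-3
      path <- enet_path_predict(xs, yc, alpha_grid[a], lmax * ratios, xnew,
                                tol, as.integer(max_sweeps))
      preds[i, a, ] <- path$predictions + ybar
    }
  }

  cv_mse_grid <- apply(preds, c(2, 3), function(p) mean((y - p)^2))
  dimnames(cv_mse_grid) <- list(alpha = as.character(alpha_grid), lambda_index = NULL)
  best <- which(cv_mse_grid == min(cv_mse_grid), arr.ind = TRUE, useNames = FALSE)
  # ties: larger lambda (smaller path index), then larger alpha
  best <- best[order(best[, 2L], -best[, 1L]), , drop = FALSE][1L, ]
  best <- c(row = best[1L], col = best[2L])
  a_star <- alpha_grid[best[["row"]]]

  # full-data path value at the winning index, and the final model
  centers <- colMeans(x)
  scales <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scales[scales == 0 | is.na(scales)] <- 1
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  lmax_full <- max(abs(crossprod(xs, y - mean(y)))) / (n * max(a_star, 1e-3))
  if (lmax_full <= 0) lmax_full <- 1e-3
  l_star <- lmax_full * ratios[best[["col"]]]
  model <- fit_elastic_net(x, y, a_star, l_star, standardize = standardize,
                           tol = tol, max_sweeps = max_sweeps)

  pairs <- data.frame(sample = rownames(x) %||% as.character(seq_len(n)),
                      observed = y,
                      predicted = preds[, best[["row"]], best[["col"]]],
                      stringsAsFactors = FALSE)
  structure(list(alpha = a_star, lambda = l_star,
                 cv_mse = mse(pairs$observed, pairs$predicted),
                 cv_mse_grid = cv_mse_grid, lambda_ratios = ratios,
                 cv_predictions = preds,
                 pairs = pairs, model = model,
                 selected_features = names(model$coefficients)[model$coefficients != 0]),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result: alpha %.2f, lambda %.4g, LOOCV MSE %.4f, %d features selected>\n",
              x$alpha, x$lambda, x$cv_mse, length(x$selected_features)))
  invisible(x)
}

# Per-product Level-3 design matrix: product-sample intensities (replicates
# averaged per product) on the sqrt scale, products as rows.
level3_matrix <- function(table) {
  cols <- product_columns(table)
  if (!length(cols)) stop("no product samples in table", call. = FALSE)
  M <- table$intensities[, cols, drop = FALSE]
  if (!table$sqrt_transformed) M <- sqrt(M)
  M[is.na(M)] <- 0
  pids <- table$samples$product_id[cols]
  X <- t(vapply(split(seq_along(pids), pids),
                function(idx) rowMeans(M[, idx, drop = FALSE]),
                numeric(nrow(M))))
  colnames(X) <- rownames(table$intensities)
  X
}

#' Level-3 comparison: predict one sensory attribute from each platform
#'
#' Runs [tune_and_evaluate()] once per platform on the identical response
#' (the per-product mean standardised attribute) so the two LOOCV MSEs are
#' directly comparable. MSEs for different attributes are not comparable to
#' each other.
#'
#' @param table_a,table_b [feature_table()] objects sharing the sensory
#'   product set.
#' @param std_sensory a [standardize_sensory()] result.
#' @param attribute attribute to predict.
#' @param ... passed on to [tune_and_evaluate()].
#' @return A list with `attribute`, per-platform `prediction_result`s `a` and
#'   `b`, and `mse_a`, `mse_b`.
#' @export
compare_platforms_level3 <- function(table_a, table_b, std_sensory, attribute, ...) {
  y_all <- product_means(std_sensory, attribute)
  run <- function(tab) {
    X <- level3_matrix(tab)
    missing_products <- setdiff(names(y_all), rownames(X))
    if (length(missing_products)) {
      stop(sprintf("platform '%s' lacks sensory products: %s", tab$platform_name,
                   paste(missing_products, collapse = ", ")), call. = FALSE)
    }
    y <- y_all[!is.na(y_all)]
    tune_and_evaluate(X[names(y), , drop = FALSE], y, ...)
  }
  res_a <- run(table_a)
  res_b <- run(table_b)
  list(attribute = attribute, a = res_a, b = res_b,
       mse_a = res_a$cv_mse, mse_b = res_b$cv_mse)
}
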