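#' Build a binary group contrast from the product design
#'
#' Encodes one discrimination question, e.g. "products containing yeast
#' product O-31 vs all others" or "olive vs corn oil", as a 0/1 label per
#' product.
#'
#' @param design a [design_table()].
#' @param factor_name design factor column to contrast on.
#' @param positive_level level of that factor defining the positive class.
#' @return An object of class `group_contrast`: list with `name`, `labels`
#'   (named 0/1 integer vector over products), `n_positive`, `n_negative`.
#' @export
contrast_from_design <- function(design, factor_name, positive_level) {
  stopifnot(inherits(design, "design_table"))
  if (!factor_name %in% names(design)) {
    stop(sprintf("factor '%s' not in design", factor_name), call. = FALSE)
  }
  labels <- as.integer(design[[factor_name]] == positive_level)
  names(labels) <- design$product_id
  if (sum(labels) == 0L) {
    stop(sprintf("level '%s' absent from factor '%s'", positive_level, factor_name), call. = FALSE)
  }
  if (sum(labels) == length(labels)) {
    stop(sprintf("level '%s' covers every product: empty negative class", positive_level),
         call. = FALSE)
  }
  structure(list(name = sprintf("%s == %s", factor_name, positive_level),
                 labels = labels, n_positive = sum(labels),
                 n_negative = sum(labels == 0L)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast '%s': %d positive vs %d negative>\n",
              x$name, x$n_positive, x$n_negative))
  invisible(x)
}

#' Point-biserial correlation of a feature with a binary contrast
#'
#' The point-biserial correlation between a continuous variable and a
#' dichotomous group indicator equals the Pearson correlation computed with
#' the indicator dummy-coded 0/1; that equivalence is how it is computed
#' here. Used as the univariate Level-2 screen: the distribution of these
#' correlations across features shows how many metabolites separate the
#' groups on their own.
#'
#' @param values per-sample feature intensities.
#' @param labels 0/1 group indicator of the same length (or a
#'   `group_contrast` whose labels are matched by name).
#' @return Correlation in \[-1, 1\]; `NA` when the values have zero variance.
#' @export
point_biserial <- function(values, labels) {
  if (inherits(labels, "group_contrast")) labels <- labels$labels
  labels <- as.numeric(labels)
  if (length(values) != length(labels)) stop("values and labels differ in length", call. = FALSE)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (length(unique(labels)) != 2L) stop("both groups must be non-empty", call. = FALSE)
  if (stats::sd(values) == 0) return(NA_real_)
  stats::cor(values, labels)
}

#' Balanced error rate from a confusion matrix
#'
#' BER = 1 - (sensitivity + specificity) / 2, i.e. the mean of the per-class
#' error rates. Unlike overall accuracy it is not dominated by the majority
#' class, which matters for unbalanced contrasts such as 7 vs 20 products.
#'
#' @param tp,fn,tn,fp confusion-matrix counts (true/false positives/negatives).
#' @return BER in \[0, 1\].
#' @examples
#' ber(3, 1, 10, 2)  # 0.2083...
#' @export
ber <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn < 1 || tn + fp < 1) stop("each class needs at least one sample", call. = FALSE)
  1 - 0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

# --- PLS1 core ---------------------------------------------------------------
# NIPALS on column-centred X (n x p) and centred response y; X is deflated,
# y is not. Returns weights W, loadings P, scores T, inner coefficients q and
# the regression vector b = W (P'W)^-1 q.
pls1_nipals <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  if (ncomp > min(n - 1L, p)) {
    stop(sprintf("n_components = %d exceeds min(samples-1, features) = %d",
                 ncomp, min(n - 1L, p)), call. = FALSE)
  }
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  X <- Xc
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # response already fully deflated / orthogonal
      W <- W[, seq_len(h - 1L), drop = FALSE]; P <- P[, seq_len(h - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(h - 1L), drop = FALSE]; q <- q[seq_len(h - 1L)]
      break
    }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(X, t)) / tt
    W[, h] <- w; P[, h] <- pl; Tm[, h] <- t; q[h] <- sum(yc * t) / tt
    X <- X - tcrossprod(t, pl)
  }
  b <- if (ncol(W)) drop(W %*% solve(crossprod(P, W), q[seq_len(ncol(W))])) else numeric(p)
  list(W = W, P = P, scores = Tm, q = q, b = b)
}

# Extract the Level-2 design matrix from a feature table: product samples as
# rows, features as columns, sqrt-transformed; plus 0/1 labels per sample.
level2_matrix <- function(table, contrast) {
  stopifnot(inherits(table, "feature_table"), inherits(contrast, "group_contrast"))
  cols <- product_columns(table)
  if (!length(cols)) stop("no product samples in table", call. = FALSE)
  pids <- table$samples$product_id[cols]
  miss <- setdiff(pids, names(contrast$labels))
  if (length(miss)) {
    stop(sprintf("products without contrast label: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  X <- t(table$intensities[, cols, drop = FALSE])
  if (!table$sqrt_transformed) X <- sqrt(X)
  X[is.na(X)] <- 0  # absent = not detected
  rownames(X) <- table$samples$sample_id[cols]
  y <- as.numeric(contrast$labels[pids])
  if (length(unique(y)) != 2L) stop("both classes must occur among the product samples", call. = FALSE)
  list(X = X, y = y, product_id = pids)
}

#' Fit a PLS-DA model for a binary product contrast
#'
#' Partial least squares discriminant analysis on the square-root
#' transformed, column-centred product-sample intensities against the
#' mean-centred 0/1 group indicator. Components are extracted sequentially
#' (NIPALS), each maximising covariance between the deflated data and the
#' response. Class prediction thresholds the projected response at the
#' midpoint of the two training-class mean predictions, which keeps the rule
#' honest for unbalanced contrasts.
#'
#' @param table a [feature_table()] (sqrt-transformed or raw; raw data is
#'   transformed internally and the flag recorded).
#' @param contrast a [contrast_from_design()] result.
#' @param n_components number of latent variables (default 2); must not
#'   exceed min(samples - 1, features).
#' @return An object of class `plsda`: weights, loadings, scores, regression
#'   vector `b`, preprocessing metadata and the decision threshold.
#' @export
fit_plsda <- function(table, contrast, n_components = 2) {
  d <- level2_matrix(table, contrast)
  fit_plsda_matrix(d$X, d$y, n_components,
                   platform_name = table$platform_name, contrast_name = contrast$name)
}

# matrix-level fitting (shared by fit_plsda and the CV folds)
fit_plsda_matrix <- function(X, y, n_components, platform_name = "", contrast_name = "") {
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  ybar <- mean(y)
  fit <- pls1_nipals(Xc, y - ybar, n_components)
  pred <- drop(Xc %*% fit$b) + ybar
  m1 <- mean(pred[y == 1]); m0 <- mean(pred[y == 0])
  structure(list(n_components = ncol(fit$W), weights = fit$W, loadings = fit$P,
                 scores = fit$scores, q = fit$q, b = fit$b,
                 centers = centers, y_mean = ybar,
                 class_means = c(negative = m0, positive = m1),
                 decision_threshold = (m0 + m1) / 2,
                 feature_ids = colnames(X),
                 platform_name = platform_name, contrast_name = contrast_name),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda%s: %d component(s), %d features%s>\n",
              if (nzchar(x$platform_name)) paste0(" '", x$platform_name, "'") else "",
              x$n_components, length(x$b),
              if (nzchar(x$contrast_name)) paste0(", contrast ", x$contrast_name) else ""))
  invisible(x)
}

#' Predict from a fitted PLS-DA model
#'
#' @param object a `plsda` model.
#' @param newdata matrix of samples x features on the same (sqrt) scale the
#'   model was trained on.
#' @param type `"response"` for the continuous projected response,
#'   `"class"` for 0/1 labels via the stored midpoint threshold.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) stop("newdata has wrong number of features", call. = FALSE)
  pred <- drop(sweep(newdata, 2, object$centers) %*% object$b) + object$y_mean
  if (type == "response") return(pred)
  pos_high <- object$class_means[["positive"]] >= object$class_means[["negative"]]
  as.integer(if (pos_high) pred >= object$decision_threshold else pred < object$decision_threshold)
}

#' Cross-validated PLS-DA balanced error rate
#'
#' Stratified k-fold cross-validation of [fit_plsda()]: folds preserve the
#' class ratio (required for contrasts as small as 7 positives), every fold's
#' preprocessing (centering, decision threshold) is computed on its training
#' split only, and the out-of-fold confusion counts are pooled into a single
#' balanced error rate. Deterministic given `seed`.
#'
#' @inheritParams fit_plsda
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `discrimination_result`: list with `ber`,
#'   `confusion` (tp, fn, tn, fp), `folds`, `n_components`, `fold_assignment`.
#' @export
cv_plsda <- function(table, contrast, n_components = 2, folds = 5, seed = 1) {
  d <- level2_matrix(table, contrast)
  cv_plsda_matrix(d$X, d$y, n_components, folds, seed)
}

cv_plsda_matrix <- function(X, y, n_components = 2, folds = 5, seed = 1) {
  n <- length(y)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (min(sum(y == 1), sum(y == 0)) < folds) {
    stop(sprintf("smallest class (%d samples) cannot be stratified over %d folds",
                 min(sum(y == 1), sum(y == 0)), folds), call. = FALSE)
  }
  assign_fold <- integer(n)
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  tp <- fn <- tn <- fp <- 0L
  for (k in seq_len(folds)) {
    te <- assign_fold == k
    fit <- fit_plsda_matrix(X[!te, , drop = FALSE], y[!te], n_components)
    pred <- predict(fit, X[te, , drop = FALSE], type = "class")
    tp <- tp + sum(pred == 1 & y[te] == 1)
    fn <- fn + sum(pred == 0 & y[te] == 1)
    tn <- tn + sum(pred == 0 & y[te] == 0)
    fp <- fp + sum(pred == 1 & y[te] == 0)
  }
  structure(list(ber = ber(tp, fn, tn, fp),
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 folds = folds, n_components = n_components, seed = seed,
                 fold_assignment = assign_fold),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result: BER %.3f over %d folds (tp %d, fn %d, tn %d, fp %d)>\n",
              x$ber, x$folds, x$confusion[["tp"]], x$confusion[["fn"]],
              x$confusion[["tn"]], x$confusion[["fp"]]))
  invisible(x)
}

#' Selectivity ratios from a fitted PLS-DA model
#'
#' Target-projection variable importance: the data are projected onto the
#' normalised PLS regression vector, reconstructed from that single target
#' component, and each feature is scored by its ratio of explained to
#' residual variance on that component. Features with a selectivity ratio
#' above 1 carry more discriminating than residual variance and form the
#' reportable set. Features whose residual variance is (numerically) zero are
#' flagged `Inf`.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param table the [feature_table()] the model was fitted on (or any table
#'   with the same features).
#' @return Named numeric vector of selectivity ratios per feature.
#' @export
selectivity_ratio <- function(model, table) {
  stopifnot(inherits(model, "plsda"))
  cols <- product_columns(table)
  X <- t(table$intensities[, cols, drop = FALSE])
  if (!table$sqrt_transformed) X <- sqrt(X)
  X[is.na(X)] <- 0
  if (ncol(X) != length(model$b)) stop("table does not match the fitted model", call. = FALSE)
  Xc <- sweep(X, 2, model$centers)
  nb <- sqrt(sum(model$b^2))
  if (nb < 1e-300) stop("regression vector is zero; selectivity undefined", call. = FALSE)
  w <- model$b / nb
  t_tp <- drop(Xc %*% w)
  p_tp <- drop(crossprod(Xc, t_tp)) / sum(t_tp^2)
  Xhat <- tcrossprod(t_tp, p_tp)
  expl <- colSums(Xhat^2)
  resid <- colSums((Xc - Xhat)^2)
  sr <- ifelse(resid <= .Machine$double.eps * pmax(expl, 1), Inf, expl / resid)
  names(sr) <- model$feature_ids
  sr
}

#' Full Level-2 discrimination analysis for one platform and contrast
#'
#' Convenience wrapper combining the univariate screen (per-feature
#' point-biserial correlations), the cross-validated PLS-DA balanced error
#' rate, and selectivity ratios from the full-data model.
#'
#' @inheritParams cv_plsda
#' @return A list with `cv` (a `discrimination_result`), `model` (full-data
#'   `plsda`), `selectivity` and `point_biserial` (named per-feature vectors).
#' @export
discriminate <- function(table, contrast, n_components = 2, folds = 5, seed = 1) {
  d <- level2_matrix(table, contrast)
  pb <- apply(d$X, 2, function(v) if (stats::sd(v) == 0) NA_real_ else stats::cor(v, d$y))
  model <- fit_plsda(table, contrast, n_components)
  list(cv = cv_plsda(table, contrast, n_components, folds, seed),
       model = model,
       selectivity = selectivity_ratio(model, table),
       point_biserial = pb)
}
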