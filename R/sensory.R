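#' Standardise sensory panel scores per panellist and attribute
#'
#' Panellists differ in the level and in the range of the 0-100 line scale
#' they use. Within each (panellist, attribute) stratum the scores over all
#' products (and sessions) are z-scored,
#' \deqn{\tilde y_{ijk} = (y_{ijk} - \bar y_{ik}) / s_{ik},}
#' with \eqn{\bar y_{ik}} and \eqn{s_{ik}} the stratum mean and sample
#' standard deviation. This removes both the level effect (a panellist
#' scoring uniformly high or low) and the scale effect (a panellist using a
#' narrow slice of the scale). Strata with zero standard deviation carry no
#' product information and are excluded with a warning.
#'
#' @param sensory a [sensory_table()].
#' @return An object of class `standardized_sensory`: list with `records`
#'   (the input rows plus `standardized_intensity`), `stratum_stats`
#'   (per-(panellist, attribute) mean/sd/n) and `excluded_strata`.
#' @export
standardize_sensory <- function(sensory) {
  stopifnot(inherits(sensory, "sensory_table"))
  df <- as.data.frame(sensory)
  key <- interaction(df$panellist_id, df$attribute, drop = TRUE, sep = "\r")
  stats_by <- lapply(split(df$intensity, key), function(x) {
    c(mean = mean(x), sd = stats::sd(x), n = length(x))
  })
  st <- do.call(rbind, stats_by)
  parts <- do.call(rbind, strsplit(rownames(st), "\r", fixed = TRUE))
  stratum_stats <- data.frame(panellist_id = parts[, 1], attribute = parts[, 2],
                              mean = st[, "mean"], sd = st[, "sd"], n = st[, "n"],
                              stringsAsFactors = FALSE, row.names = NULL)
  degenerate <- is.na(stratum_stats$sd) | stratum_stats$sd == 0
  if (any(degenerate)) {
    warning(sprintf("excluding %d constant-scoring (panellist, attribute) stratum/strata: %s",
                    sum(degenerate),
                    paste(utils::head(paste(stratum_stats$panellist_id[degenerate],
                                            stratum_stats$attribute[degenerate], sep = "/"), 5),
                          collapse = ", ")),
            call. = FALSE)
  }
  mu <- stats::setNames(stratum_stats$mean, rownames(st))
  sig <- stats::setNames(stratum_stats$sd, rownames(st))
  sig[degenerate] <- NA_real_
  kchr <- as.character(key)
  df$standardized_intensity <- (df$intensity - mu[kchr]) / sig[kchr]
  keep <- !is.na(df$standardized_intensity)
  structure(list(records = df[keep, , drop = FALSE],
                 stratum_stats = stratum_stats[!degenerate, , drop = FALSE],
                 excluded_strata = stratum_stats[degenerate, c("panellist_id", "attribute"),
                                                 drop = FALSE]),
            class = "standardized_sensory")
}

#' @export
print.standardized_sensory <- function(x, ...) {
  cat(sprintf("<standardized_sensory: %d records, %d panellists, %d attributes (%d strata excluded)>\n",
              nrow(x$records), length(unique(x$records$panellist_id)),
              length(unique(x$records$attribute)), nrow(x$excluded_strata)))
  invisible(x)
}

#' Per-product mean standardised score for one attribute
#'
#' Averages the standardised scores over panellists (and sessions) within
#' each product; this is the per-product response used by the Level-3
#' regression. Products never assessed for the attribute are returned as
#' `NA`.
#'
#' @param std a [standardize_sensory()] result.
#' @param attribute attribute name.
#' @param products optional product ids fixing the output order; defaults to
#'   the products observed for this attribute (sorted).
#' @return Named numeric vector of per-product means.
#' @export
product_means <- function(std, attribute, products = NULL) {
  stopifnot(inherits(std, "standardized_sensory"))
  rec <- std$records[std$records$attribute == attribute, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("attribute '%s' not present", attribute), call. = FALSE)
  m <- tapply(rec$standardized_intensity, rec$product_id, mean)
  if (is.null(products)) products <- sort(names(m))
  out <- stats::setNames(as.numeric(m[products]), products)
  out
}

#' F-test for product differences in one attribute
#'
#' One-way fixed-effects analysis of variance of the standardised scores on
#' product, used as a screen for whether the design induced sufficient
#' variation in the attribute before trying to predict it from metabolite
#' levels.
#'
#' @inheritParams product_means
#' @return A list with `statistic` (F), `p_value`, `df` (numerator,
#'   denominator).
#' @export
attribute_variation_test <- function(std, attribute) {
  stopifnot(inherits(std, "standardized_sensory"))
  rec <- std$records[std$records$attribute == attribute, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("attribute '%s' not present", attribute), call. = FALSE)
  if (length(unique(rec$product_id)) < 2L) stop("need >= 2 products for an F-test", call. = FALSE)
  if (nrow(rec) <= length(unique(rec$product_id))) {
    stop("no replication: F-test undefined", call. = FALSE)
  }
  a <- stats::anova(stats::lm(standardized_intensity ~ factor(product_id), data = rec))
  list(statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1],
       df = c(a$Df[1], a$Df[2]))
}

#' Skewness diagnostic for one attribute's standardised scores
#'
#' Reports the sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} and flags the
#' attribute when |g1| exceeds `threshold` (default 1, a conventional
#' screening value), signalling that a variance-stabilising transformation
#' may be warranted before regression. No transformation is applied
#' automatically.
#'
#' @inheritParams product_means
#' @param threshold |skewness| flag threshold.
#' @return A list with `skewness` (`NA` for constant scores), `flagged`,
#'   `threshold`, `n`.
#' @export
check_skewness <- function(std, attribute, threshold = 1) {
  stopifnot(inherits(std, "standardized_sensory"))
  x <- std$records$standardized_intensity[std$records$attribute == attribute]
  if (!length(x)) stop(sprintf("attribute '%s' not present", attribute), call. = FALSE)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  g1 <- if (m2 <= .Machine$double.eps) NA_real_ else mean((x - mean(x))^3) / m2^1.5
  list(skewness = g1, flagged = isTRUE(abs(g1) > threshold),
       threshold = threshold, n = n)
}
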