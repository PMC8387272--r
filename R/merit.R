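#' Relative standard deviation over QC replicates
#'
#' RSD = sample standard deviation (n-1 denominator) divided by the mean, on
#' raw (untransformed) intensities. Missing values are dropped before the
#' computation; at least two finite values and a positive mean are required.
#'
#' @param qc_values numeric vector of replicate QC intensities for one feature.
#' @return The RSD (dimensionless).
#' @examples
#' compute_rsd(c(8, 10, 12))  # 0.2
#' @export
compute_rsd <- function(qc_values) {
  x <- qc_values[!is.na(qc_values)]
  if (length(x) < 2L) stop("RSD needs at least 2 QC replicates", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("RSD undefined for non-positive mean", call. = FALSE)
  stats::sd(x) / m
}

#' Intensity range over product samples
#'
#' Range = max - min intensity across the product samples; a wider range
#' across the same products indicates higher sensitivity for that compound.
#' Missing values are dropped.
#'
#' @param product_values numeric vector of product-sample intensities.
#' @return The range (same units as the intensities).
#' @export
compute_range <- function(product_values) {
  x <- product_values[!is.na(product_values)]
  if (length(x) == 0L) stop("range needs at least 1 value", call. = FALSE)
  max(x) - min(x)
}

#' Level-1 figures of merit for one platform
#'
#' Metabolite-independent summary: per-feature QC mean, QC RSD and product
#' intensity range, plus the fraction of features whose RSD falls below the
#' reporting threshold (conventionally 0.20). RSD is undefined (NA, counted
#' in `n_undefined_rsd`) for features with fewer than two finite QC values or
#' non-positive QC mean.
#'
#' @param table a [feature_table()] with at least two QC samples.
#' @param rsd_threshold RSD reporting threshold; default 0.20.
#' @return An object of class `merit_report`: list with `per_feature`
#'   (data frame `feature_id`, `mean_qc`, `rsd`, `range`), `platform_name`,
#'   `rsd_threshold`, `fraction_below_threshold`, `n_undefined_rsd`.
#' @export
merit_report <- function(table, rsd_threshold = 0.20) {
  stopifnot(inherits(table, "feature_table"))
  qc <- qc_columns(table)
  if (length(qc) < 2L) stop("merit report needs at least 2 QC samples", call. = FALSE)
  prod <- product_columns(table)
  M <- table$intensities
  per <- data.frame(feature_id = rownames(M), mean_qc = NA_real_,
                    rsd = NA_real_, range = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(M))) {
    q <- M[i, qc][!is.na(M[i, qc])]
    if (length(q) >= 1L) per$mean_qc[i] <- mean(q)
    if (length(q) >= 2L && mean(q) > 0) per$rsd[i] <- stats::sd(q) / mean(q)
    p <- M[i, prod][!is.na(M[i, prod])]
    if (length(p) >= 1L) per$range[i] <- max(p) - min(p)
  }
  defined <- !is.na(per$rsd)
  structure(list(per_feature = per, platform_name = table$platform_name,
                 rsd_threshold = rsd_threshold,
                 fraction_below_threshold = if (any(defined)) mean(per$rsd[defined] < rsd_threshold) else NA_real_,
                 n_undefined_rsd = sum(!defined)),
            class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat(sprintf("<merit_report '%s': %d features, median RSD %.3f, %.1f%% below %.2f (%d undefined)>\n",
              x$platform_name, nrow(x$per_feature),
              stats::median(x$per_feature$rsd, na.rm = TRUE),
              100 * x$fraction_below_threshold, x$rsd_threshold, x$n_undefined_rsd))
  invisible(x)
}

#' Metabolite-dependent merit comparison over common metabolites
#'
#' Pairs the two platforms' figures of merit feature-by-feature across the
#' common metabolites and counts how many pairs lie above/below the identity
#' diagonal of the RSD scatter (above = higher RSD, i.e. worse precision, on
#' platform B). Pairs with an undefined RSD on either side are excluded and
#' counted separately.
#'
#' @param report_a,report_b [merit_report()] objects for the two platforms.
#' @param matchset the [find_common_metabolites()] result linking them.
#' @return A list with `paired` (data frame `feature_a`, `feature_b`,
#'   `rsd_a`, `rsd_b`, `range_a`, `range_b`), `n_above_diagonal` (rsd_b >
#'   rsd_a), `n_below_diagonal`, `n_on_diagonal`, `n_excluded`.
#' @export
compare_common_merit <- function(report_a, report_b, matchset) {
  stopifnot(inherits(report_a, "merit_report"), inherits(report_b, "merit_report"),
            inherits(matchset, "match_set"))
  pa <- report_a$per_feature; rownames(pa) <- pa$feature_id
  pb <- report_b$per_feature; rownames(pb) <- pb$feature_id
  bad <- c(setdiff(matchset$pairs$feature_a, pa$feature_id),
           setdiff(matchset$pairs$feature_b, pb$feature_id))
  if (length(bad)) {
    stop(sprintf("match set references features absent from the merit reports: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  paired <- data.frame(feature_a = matchset$pairs$feature_a,
                       feature_b = matchset$pairs$feature_b,
                       rsd_a = pa[matchset$pairs$feature_a, "rsd"],
                       rsd_b = pb[matchset$pairs$feature_b, "rsd"],
                       range_a = pa[matchset$pairs$feature_a, "range"],
                       range_b = pb[matchset$pairs$feature_b, "range"],
                       stringsAsFactors = FALSE)
  rownames(paired) <- NULL
  ok <- !is.na(paired$rsd_a) & !is.na(paired$rsd_b)
  list(paired = paired[ok, , drop = FALSE],
       n_above_diagonal = sum(paired$rsd_b[ok] > paired$rsd_a[ok]),
       n_below_diagonal = sum(paired$rsd_b[ok] < paired$rsd_a[ok]),
       n_on_diagonal = sum(paired$rsd_b[ok] == paired$rsd_a[ok]),
       n_excluded = sum(!ok))
}
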