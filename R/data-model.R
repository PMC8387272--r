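#' Construct a mass spectrum
#'
#' A mass spectrum is the list of (m/z, intensity) peaks recorded for one
#' deconvoluted GC-MS feature. m/z values must be unique, intensities finite
#' and non-negative, and at least one peak must carry positive intensity.
#'
#' @param mz numeric vector of m/z values (positive, unique).
#' @param intensity numeric vector of peak intensities (non-negative, finite),
#'   same length as `mz`.
#' @return An object of class `mass_spectrum` with components `mz` and
#'   `intensity`, sorted by increasing m/z.
#' @examples
#' mass_spectrum(c(41, 55), c(100, 25))
#' @export
mass_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (length(mz) == 0L) stop("spectrum must contain at least one peak", call. = FALSE)
  if (anyNA(mz) || any(!is.finite(mz)) || any(mz <= 0)) {
    stop("m/z values must be finite and positive", call. = FALSE)
  }
  if (anyDuplicated(mz)) stop("m/z values must be unique within a spectrum", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!any(intensity > 0)) stop("spectrum must have at least one peak with intensity > 0", call. = FALSE)
  ord <- order(mz)
  structure(list(mz = mz[ord], intensity = intensity[ord]), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum: %d peaks, m/z %g-%g, base peak %g>\n",
              length(x$mz), min(x$mz), max(x$mz), x$mz[which.max(x$intensity)]))
  invisible(x)
}

#' Construct a feature (one detected metabolite)
#'
#' A feature is a deconvoluted GC-MS signal: an id, a retention index, its
#' mass spectrum and, optionally, an annotation (compound name). Features
#' without a spectrum are kept but are not eligible for spectral matching.
#'
#' @param feature_id character scalar, unique within a platform.
#' @param retention_index non-negative finite number (retention-index units).
#' @param spectrum a [mass_spectrum()] or `NULL`.
#' @param annotation optional compound name (`NA` if unannotated).
#' @return An object of class `feature`.
#' @export
feature <- function(feature_id, retention_index, spectrum = NULL, annotation = NA_character_) {
  if (!is.character(feature_id) || length(feature_id) != 1L || is.na(feature_id) || !nzchar(feature_id)) {
    stop("feature_id must be a non-empty character scalar", call. = FALSE)
  }
  retention_index <- as.numeric(retention_index)
  if (length(retention_index) != 1L || !is.finite(retention_index) || retention_index < 0) {
    stop(sprintf("retention_index for '%s' must be a finite non-negative number", feature_id),
         call. = FALSE)
  }
  if (!is.null(spectrum) && !inherits(spectrum, "mass_spectrum")) {
    stop("spectrum must be a mass_spectrum or NULL", call. = FALSE)
  }
  structure(list(feature_id = feature_id, retention_index = retention_index,
                 spectrum = spectrum,
                 annotation = if (is.na(annotation)) NA_character_ else as.character(annotation)),
            class = "feature")
}

#' Construct a per-platform feature table
#'
#' The central container for one platform: an intensity matrix of features by
#' samples plus per-sample roles. Samples are products (carry a `product_id`),
#' pooled quality-control injections (`qc`) or blanks (`blank`). Blanks are
#' stored but excluded from all downstream statistics.
#'
#' @param platform_name character scalar naming the platform/method.
#' @param features list of [feature()] objects; ids must be unique and match
#'   `rownames(intensities)`.
#' @param samples data frame with columns `sample_id`, `role` (one of
#'   `"product"`, `"qc"`, `"blank"`) and `product_id` (required for products,
#'   `NA` otherwise).
#' @param intensities numeric matrix, features x samples, non-negative;
#'   missing measurements are `NA`.
#' @param sqrt_transformed logical flag; set by [sqrt_transform()].
#' @return An object of class `feature_table`.
#' @seealso [read_feature_table()], [write_feature_table()], [sqrt_transform()]
#' @export
feature_table <- function(platform_name, features, samples, intensities,
                          sqrt_transformed = FALSE) {
  if (!is.character(platform_name) || length(platform_name) != 1L || !nzchar(platform_name)) {
    stop("platform_name must be a non-empty character scalar", call. = FALSE)
  }
  if (!is.list(features) || length(features) == 0L ||
      !all(vapply(features, inherits, logical(1), "feature"))) {
    stop("features must be a non-empty list of feature objects", call. = FALSE)
  }
  ids <- vapply(features, `[[`, character(1), "feature_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate feature ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  names(features) <- ids
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "role", "product_id")
  if (!all(req %in% names(samples))) {
    stop("samples must have columns sample_id, role, product_id", call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$role <- as.character(samples$role)
  samples$product_id <- as.character(samples$product_id)
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique", call. = FALSE)
  bad_role <- setdiff(unique(samples$role), c("product", "qc", "blank"))
  if (length(bad_role)) {
    stop(sprintf("unknown sample role(s): %s", paste(bad_role, collapse = ", ")), call. = FALSE)
  }
  no_pid <- samples$role == "product" & (is.na(samples$product_id) | !nzchar(samples$product_id))
  if (any(no_pid)) {
    stop(sprintf("product samples without product_id: %s",
                 paste(samples$sample_id[no_pid], collapse = ", ")), call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(features) || ncol(intensities) != nrow(samples)) {
    stop(sprintf("intensity matrix is %d x %d but there are %d features and %d samples",
                 nrow(intensities), ncol(intensities), length(features), nrow(samples)),
         call. = FALSE)
  }
  if (is.null(rownames(intensities))) rownames(intensities) <- ids
  if (is.null(colnames(intensities))) colnames(intensities) <- samples$sample_id
  if (!identical(rownames(intensities), unname(ids))) {
    off <- setdiff(rownames(intensities), ids)
    stop(sprintf("intensity row names do not match feature ids (offending: %s)",
                 paste(utils::head(c(off, setdiff(ids, rownames(intensities))), 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(colnames(intensities), samples$sample_id)) {
    off <- setdiff(colnames(intensities), samples$sample_id)
    stop(sprintf("intensity column names do not match sample ids (offending: %s)",
                 paste(utils::head(c(off, setdiff(samples$sample_id, colnames(intensities))), 5), collapse = ", ")),
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(platform_name = platform_name, features = features,
                 samples = samples, intensities = intensities,
                 sqrt_transformed = isTRUE(sqrt_transformed)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  roles <- table(factor(x$samples$role, levels = c("product", "qc", "blank")))
  cat(sprintf("<feature_table '%s': %d features x %d samples (%d product, %d QC, %d blank)%s>\n",
              x$platform_name, nrow(x$intensities), ncol(x$intensities),
              roles[["product"]], roles[["qc"]], roles[["blank"]],
              if (x$sqrt_transformed) ", sqrt-transformed" else ""))
  n_spec <- sum(vapply(x$features, function(f) !is.null(f$spectrum), logical(1)))
  n_ann <- sum(vapply(x$features, function(f) !is.na(f$annotation), logical(1)))
  cat(sprintf("  spectra for %d features; %d annotated\n", n_spec, n_ann))
  invisible(x)
}

# column indices by role, blanks always excluded from statistics
qc_columns <- function(table) which(table$samples$role == "qc")
product_columns <- function(table) which(table$samples$role == "product")

#' Square-root transform a feature table
#'
#' Applies an element-wise square root to the intensity matrix to correct for
#' the multiplicative (heteroscedastic) error structure of GC-MS intensities
#' before the Level 2/3 analyses. Guarded so it cannot be applied twice.
#'
#' @param table a [feature_table()].
#' @return The transformed `feature_table` with `sqrt_transformed = TRUE`.
#' @export
sqrt_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$sqrt_transformed) {
    stop("table is already sqrt-transformed; the transform cannot be applied twice",
         call. = FALSE)
  }
  if (any(table$intensities < 0, na.rm = TRUE)) {
    stop("negative intensities cannot be sqrt-transformed", call. = FALSE)
  }
  table$intensities <- sqrt(table$intensities)
  table$sqrt_transformed <- TRUE
  table
}

#' Construct a product design table
#'
#' Holds the compositional design: one row per product, one column per
#' design factor (e.g. oil type, yeast product, dosages). A factor level may
#' be the explicit none marker `"-"` (e.g. no yeast added) but never missing.
#'
#' @param df data frame with a `product_id` column plus one column per factor.
#' @return An object of class `design_table` (a validated data frame).
#' @export
design_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"product_id" %in% names(df)) stop("design table needs a product_id column", call. = FALSE)
  df$product_id <- as.character(df$product_id)
  if (anyDuplicated(df$product_id)) stop("duplicate product ids in design", call. = FALSE)
  if (ncol(df) < 2L) stop("design table needs at least one factor column", call. = FALSE)
  fac <- setdiff(names(df), "product_id")
  for (f in fac) {
    df[[f]] <- as.character(df[[f]])
    if (anyNA(df[[f]]) || any(!nzchar(df[[f]]))) {
      stop(sprintf("factor '%s' has missing levels; use an explicit '-' for none", f),
           call. = FALSE)
    }
  }
  structure(df, class = c("design_table", "data.frame"))
}

#' Construct a sensory panel table
#'
#' Long-format QDA panel scores: one row per (panellist, product, attribute,
#' session) assessment on an unstructured 0-100 line scale.
#'
#' @param df data frame with columns `panellist_id`, `product_id`,
#'   `attribute`, `intensity` and optionally `session` (defaults to 1).
#' @return An object of class `sensory_table` (a validated data frame).
#' @export
sensory_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("panellist_id", "product_id", "attribute", "intensity")
  if (!all(req %in% names(df))) {
    stop("sensory table needs columns panellist_id, product_id, attribute, intensity",
         call. = FALSE)
  }
  if (!"session" %in% names(df)) df$session <- 1L
  for (col in c("panellist_id", "product_id", "attribute")) df[[col]] <- as.character(df[[col]])
  df$intensity <- as.numeric(df$intensity)
  if (anyNA(df$intensity) || any(df$intensity < 0 | df$intensity > 100)) {
    stop("intensities must lie on the 0-100 line scale", call. = FALSE)
  }
  key <- paste(df$panellist_id, df$product_id, df$attribute, df$session, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (panellist, product, attribute, session) assessments", call. = FALSE)
  }
  structure(df[c("panellist_id", "product_id", "attribute", "session", "intensity")],
            class = c("sensory_table", "data.frame"))
}
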