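#' Cosine similarity between two mass spectra
#'
#' Spectra are first binned to integer nominal mass (unit-resolution
#' quadrupole data; intensities within a bin are summed), square-root
#' transformed, and zero-padded onto the union m/z axis so that masses
#' present in only one spectrum contribute zero to the other. The score is
#' the cosine of the angle between the two resulting vectors,
#' \deqn{S_{AB} = \frac{I_A \cdot I_B}{\lVert I_A\rVert\,\lVert I_B\rVert},}
#' which lies in \[0, 1\], is symmetric, and is invariant to rescaling either
#' spectrum by a positive constant.
#'
#' @param spec_a,spec_b [mass_spectrum()] objects.
#' @return Cosine similarity in \[0, 1\].
#' @examples
#' a <- mass_spectrum(c(41, 55), c(100, 25))
#' b <- mass_spectrum(c(41, 69), c(64, 36))
#' cosine_similarity(a, b)  # 0.7155...
#' @export
cosine_similarity <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "mass_spectrum"), inherits(spec_b, "mass_spectrum"))
  va <- bin_spectrum(spec_a)
  vb <- bin_spectrum(spec_b)
  mz <- union(names(va), names(vb))
  ia <- sqrt(unname(va[mz])); ia[is.na(ia)] <- 0
  ib <- sqrt(unname(vb[mz])); ib[is.na(ib)] <- 0
  na <- sqrt(sum(ia^2)); nb <- sqrt(sum(ib^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for an all-zero spectrum", call. = FALSE)
  s <- sum(ia * ib) / (na * nb)
  min(max(s, 0), 1)  # clamp float round-off
}

# sum intensities into integer nominal-mass bins; named numeric vector
bin_spectrum <- function(spec) {
  b <- round(spec$mz)
  tapply(spec$intensity, b, sum)
}

#' Find common metabolites between two platforms
#'
#' Implements the bidirectional common-metabolite procedure: (1) for each
#' feature of platform A, preselect B candidates whose retention indices
#' differ by at most `ri_tolerance`; (2) score candidates by
#' [cosine_similarity()] and keep the best; (3) repeat from B to A; (4) a
#' pair is a common metabolite only when the forward and reverse passes
#' select each other (mutual best hit) and the similarity reaches
#' `sim_threshold`. Features without spectra never enter the matcher. Ties in
#' best-hit selection are broken by smaller RI difference, then by feature id.
#'
#' @param table_a,table_b [feature_table()] objects with spectra and RIs.
#' @param ri_tolerance maximum allowed |RI_A - RI_B| for a candidate pair, in
#'   retention-index units; `Inf` disables the gate. Default 2.
#' @param sim_threshold minimum cosine similarity for acceptance, in (0, 1).
#'   Default 0.65.
#' @return An object of class `match_set`: a list with `pairs` (data frame
#'   `feature_a`, `feature_b`, `similarity`, `ri_difference`, sorted by
#'   `feature_a`), `threshold_used`, `ri_tolerance_used` and the platform
#'   names. Each feature appears in at most one pair.
#' @export
find_common_metabolites <- function(table_a, table_b, ri_tolerance = 2,
                                    sim_threshold = 0.65) {
  stopifnot(inherits(table_a, "feature_table"), inherits(table_b, "feature_table"))
  if (!is.finite(sim_threshold) || sim_threshold <= 0 || sim_threshold >= 1) {
    stop("sim_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (is.na(ri_tolerance) || ri_tolerance < 0) stop("ri_tolerance must be >= 0 (or Inf)", call. = FALSE)

  fa <- Filter(function(f) !is.null(f$spectrum), table_a$features)
  fb <- Filter(function(f) !is.null(f$spectrum), table_b$features)
  if (length(fa) == 0L || length(fb) == 0L) {
    stop("no spectra available for matching on at least one platform", call. = FALSE)
  }
  ids_a <- names(fa); ids_b <- names(fb)
  ri_a <- vapply(fa, `[[`, numeric(1), "retention_index")
  ri_b <- vapply(fb, `[[`, numeric(1), "retention_index")
  bins_a <- lapply(fa, function(f) bin_spectrum(f$spectrum))
  bins_b <- lapply(fb, function(f) bin_spectrum(f$spectrum))

  # all gated pairwise similarities, computed once (the score is symmetric,
  # so forward and reverse passes share them)
  sim <- matrix(NA_real_, length(fa), length(fb), dimnames = list(ids_a, ids_b))
  for (i in seq_along(fa)) {
    cand <- which(abs(ri_b - ri_a[i]) <= ri_tolerance)
    for (j in cand) sim[i, j] <- cosine_pre_binned(bins_a[[i]], bins_b[[j]])
  }

  best_hit <- function(scores, dri, ids) {
    ok <- which(!is.na(scores))
    if (!length(ok)) return(NA_character_)
    mx <- max(scores[ok])
    tie <- ok[scores[ok] == mx]
    if (length(tie) > 1L) {
      tie <- tie[dri[tie] == min(dri[tie])]
      if (length(tie) > 1L) tie <- tie[order(ids[tie])][1L]
    }
    ids[tie[1L]]
  }

  fwd <- vapply(seq_along(fa), function(i)
    best_hit(sim[i, ], abs(ri_b - ri_a[i]), ids_b), character(1))
  rev <- vapply(seq_along(fb), function(j)
    best_hit(sim[, j], abs(ri_a - ri_b[j]), ids_a), character(1))
  names(fwd) <- ids_a; names(rev) <- ids_b

  keep <- !is.na(fwd) & rev[fwd] == ids_a & sim[cbind(ids_a, fwd)] >= sim_threshold
  keep[is.na(keep)] <- FALSE
  pairs <- data.frame(feature_a = ids_a[keep], feature_b = unname(fwd[keep]),
                      stringsAsFactors = FALSE)
  pairs$similarity <- if (nrow(pairs)) sim[cbind(pairs$feature_a, pairs$feature_b)] else numeric(0)
  pairs$ri_difference <- if (nrow(pairs)) {
    abs(ri_a[pairs$feature_a] - ri_b[pairs$feature_b])
  } else numeric(0)
  pairs <- pairs[order(pairs$feature_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, threshold_used = sim_threshold,
                 ri_tolerance_used = ri_tolerance,
                 platform_a = table_a$platform_name,
                 platform_b = table_b$platform_name),
            class = "match_set")
}

# cosine on pre-binned named intensity vectors (internal fast path)
cosine_pre_binned <- function(va, vb) {
  mz <- union(names(va), names(vb))
  ia <- sqrt(unname(va[mz])); ia[is.na(ia)] <- 0
  ib <- sqrt(unname(vb[mz])); ib[is.na(ib)] <- 0
  sum(ia * ib) / (sqrt(sum(ia^2)) * sqrt(sum(ib^2)))
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: %d common pairs between '%s' and '%s' (threshold %.2f, RI tolerance %s)>\n",
              nrow(x$pairs), x$platform_a, x$platform_b, x$threshold_used,
              format(x$ri_tolerance_used)))
  invisible(x)
}

#' Calibrate the cosine-similarity threshold on annotated features
#'
#' The acceptance threshold can be set from the annotated (identified)
#' metabolites: annotation names shared by both platforms define the
#' ground-truth common compounds, names present on only one platform are
#' known non-commons. For every threshold in `grid` the matcher is run on the
#' annotated features only and scored by how many true commons it detects and
#' how many false commons (pairs whose annotations disagree) it admits. The
#' returned threshold is the smallest grid value with zero false commons,
#' i.e. the most sensitive operating point that stays specific.
#'
#' Annotation names are compared after case folding and whitespace trimming.
#'
#' @inheritParams find_common_metabolites
#' @param grid numeric vector of candidate thresholds in (0, 1).
#' @return A list with `threshold` (chosen value, `NA` if no grid point
#'   reaches zero false commons) and `curve`, a data frame with one row per
#'   grid value: `threshold`, `true_common`, `false_common`, `n_true_common`
#'   (number of ground-truth common compounds).
#' @export
calibrate_threshold <- function(table_a, table_b, ri_tolerance = 2,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  ann_sub <- function(tab) {
    keep <- vapply(tab$features, function(f) !is.na(f$annotation) && !is.null(f$spectrum),
                   logical(1))
    if (!any(keep)) stop(sprintf("no annotated features with spectra in '%s'", tab$platform_name),
                         call. = FALSE)
    tab$features <- tab$features[keep]
    tab$intensities <- tab$intensities[keep, , drop = FALSE]
    tab
  }
  a <- ann_sub(table_a); b <- ann_sub(table_b)
  norm_name <- function(x) tolower(trimws(x))
  ann_a <- norm_name(vapply(a$features, `[[`, character(1), "annotation"))
  ann_b <- norm_name(vapply(b$features, `[[`, character(1), "annotation"))
  truth <- intersect(ann_a, ann_b)
  if (length(truth) == 0L) stop("no annotation names shared between the platforms", call. = FALSE)

  grid <- sort(unique(grid))
  curve <- data.frame(threshold = grid, true_common = NA_integer_,
                      false_common = NA_integer_, n_true_common = length(truth))
  for (k in seq_along(grid)) {
    ms <- find_common_metabolites(a, b, ri_tolerance, grid[k])
    pa <- ann_a[ms$pairs$feature_a]
    pb <- ann_b[ms$pairs$feature_b]
    curve$true_common[k] <- length(intersect(truth, pa[pa == pb]))
    curve$false_common[k] <- sum(pa != pb)
  }
  ok <- curve$false_common == 0L
  list(threshold = if (any(ok)) grid[which(ok)[1L]] else NA_real_, curve = curve)
}

#' Partition platform features into common and unique sets
#'
#' @param table_a,table_b the matched [feature_table()] objects.
#' @param matchset the [find_common_metabolites()] result derived from them.
#' @return A list of four character vectors: `common_a_ids`, `common_b_ids`
#'   (in pair order), `unique_a_ids`, `unique_b_ids`. Within each platform
#'   the partition is disjoint and exhaustive.
#' @export
partition_features <- function(table_a, table_b, matchset) {
  stopifnot(inherits(matchset, "match_set"))
  ids_a <- names(table_a$features); ids_b <- names(table_b$features)
  bad <- c(setdiff(matchset$pairs$feature_a, ids_a),
           setdiff(matchset$pairs$feature_b, ids_b))
  if (length(bad)) {
    stop(sprintf("match set references unknown feature ids: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  list(common_a_ids = matchset$pairs$feature_a,
       common_b_ids = matchset$pairs$feature_b,
       unique_a_ids = setdiff(ids_a, matchset$pairs$feature_a),
       unique_b_ids = setdiff(ids_b, matchset$pairs$feature_b))
}
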