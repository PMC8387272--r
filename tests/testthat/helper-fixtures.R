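# Shared fixture builders. Everything is generated in code at test time.

# random unit-resolution spectrum with npeaks peaks
rand_spec <- function(npeaks = 8, mz_range = 40:300) {
  mz <- sample(mz_range, npeaks)
  mass_spectrum(mz, stats::runif(npeaks, 1, 999))
}

# minimal feature_table around given features: 2 products + 2 QCs, unit intensities
toy_table <- function(features, platform = "toy") {
  n <- length(features)
  samples <- data.frame(sample_id = c("S1", "S2", "Q1", "Q2"),
                        role = c("product", "product", "qc", "qc"),
                        product_id = c("P1", "P2", NA, NA))
  m <- matrix(1, n, 4, dimnames = list(vapply(features, `[[`, character(1), "feature_id"),
                                       samples$sample_id))
  feature_table(platform, features, samples, m)
}

# random table of spectral features for matcher tests
rand_match_table <- function(n_features, platform, ri_range = c(1000, 1100)) {
  feats <- lapply(seq_len(n_features), function(i) {
    feature(sprintf("%s%02d", platform, i), stats::runif(1, ri_range[1], ri_range[2]),
            rand_spec(sample(4:10, 1)))
  })
  toy_table(feats, platform)
}

# Independent mutual-best-hit oracle: exhaustive enumeration over all gated
# pairs using the public cosine_similarity, with the documented tie-breaks
# (smaller RI difference, then lexicographic id).
brute_force_commons <- function(table_a, table_b, ri_tolerance, sim_threshold) {
  fa <- Filter(function(f) !is.null(f$spectrum), table_a$features)
  fb <- Filter(function(f) !is.null(f$spectrum), table_b$features)
  grid <- expand.grid(a = names(fa), b = names(fb), stringsAsFactors = FALSE)
  grid$dri <- abs(vapply(fa[grid$a], `[[`, numeric(1), "retention_index") -
                    vapply(fb[grid$b], `[[`, numeric(1), "retention_index"))
  grid <- grid[grid$dri <= ri_tolerance, , drop = FALSE]
  if (!nrow(grid)) return(data.frame(feature_a = character(0), feature_b = character(0)))
  grid$sim <- mapply(function(a, b) cosine_similarity(fa[[a]]$spectrum, fb[[b]]$spectrum),
                     grid$a, grid$b)
  pick <- function(rows) {  # best candidate among rows of grid
    rows <- rows[order(-rows$sim, rows$dri, rows$a, rows$b), , drop = FALSE]
    rows[1L, ]
  }
  pairs <- character(0)
  for (a in unique(grid$a)) {
    best_ab <- pick(grid[grid$a == a, , drop = FALSE])
    best_ba <- pick(grid[grid$b == best_ab$b, , drop = FALSE])
    if (best_ba$a == a && best_ab$sim >= sim_threshold) {
      pairs <- c(pairs, paste(a, best_ab$b))
    }
  }
  out <- do.call(rbind, strsplit(sort(pairs), " "))
  if (is.null(out)) return(data.frame(feature_a = character(0), feature_b = character(0)))
  data.frame(feature_a = out[, 1], feature_b = out[, 2], stringsAsFactors = FALSE)
}

# Level-2 fixture: wrap a samples x features matrix (any real values) into a
# feature_table on the sqrt scale plus a matching design/contrast. Values are
# shifted to be positive; the shift is absorbed by the model's centering.
level2_fixture <- function(X, y) {
  X <- X - min(X) + 1
  n <- nrow(X)
  pids <- sprintf("P%03d", seq_len(n))
  samples <- data.frame(sample_id = pids, role = "product", product_id = pids)
  # add two QC columns so the table is also merit-capable
  samples <- rbind(samples, data.frame(sample_id = c("Q1", "Q2"), role = "qc",
                                       product_id = NA))
  m <- cbind(t(X), matrix(1, ncol(X), 2))
  rownames(m) <- sprintf("F%03d", seq_len(ncol(X)))
  colnames(m) <- samples$sample_id
  feats <- lapply(rownames(m), function(id) feature(id, 1000))
  tab <- feature_table("sim", feats, samples, m, sqrt_transformed = TRUE)
  design <- design_table(data.frame(product_id = pids,
                                    group = ifelse(y == 1, "pos", "neg")))
  list(table = tab, contrast = contrast_from_design(design, "group", "pos"))
}

# small generator bundle shared by several test files (computed once)
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- default_study_fixture(seed = 42, n_features_a = 60, n_features_b = 90,
                                      n_common = 30, n_annotated_common = 15,
                                      n_annotated_unique_a = 10, n_annotated_unique_b = 10)
    }
    cache
  }
})
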