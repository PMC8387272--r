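#' Run the full three-level method comparison
#'
#' Orchestrates the pipeline end to end: common-metabolite matching, Level-1
#' figures of merit (metabolite-independent and over common metabolites),
#' Level-2 discrimination per configured contrast (point-biserial screen,
#' cross-validated PLS-DA BER, selectivity ratios), sensory standardisation
#' with per-attribute F-tests, and Level-3 elastic-net prediction per
#' attribute. Deterministic given the seed in `config`.
#'
#' No automatic winner is declared: the levels may legitimately disagree
#' (one platform more precise, the other more discriminating), so the report
#' juxtaposes the evidence per level and leaves the selection to the user.
#'
#' @param table_a,table_b per-platform [feature_table()] objects.
#' @param design a [design_table()].
#' @param sensory a [sensory_table()], or `NULL` to skip Level 3 and the
#'   sensory screens (the report marks them skipped).
#' @param config list of settings: `contrasts` (list of
#'   `list(factor, level)`), `attributes` (character), `ri_tolerance`,
#'   `sim_threshold`, `n_components`, `folds`, `seed`, `rsd_threshold`,
#'   `alpha_grid`, `nlambda`. Missing entries take the defaults below.
#' @param out_dir optional directory; when given, `report.json` and the
#'   per-stage CSV files are written there.
#' @return An object of class `comparison_report`.
#' @export
run_full_comparison <- function(table_a, table_b, design, sensory = NULL,
                                config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    contrasts = list(list(factor = "yeast_product", level = "Maxagusto O-31"),
                     list(factor = "oil_type", level = "Olive")),
    attributes = c("intensity.od", "umami.fl"),
    ri_tolerance = 2, sim_threshold = 0.65,
    n_components = 2, folds = 5, seed = 1, rsd_threshold = 0.20,
    alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1), nlambda = 50), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  matches <- stage("match", find_common_metabolites(table_a, table_b,
                                                    cfg$ri_tolerance, cfg$sim_threshold))
  parts <- partition_features(table_a, table_b, matches)

  merit_a <- stage("merit", merit_report(table_a, cfg$rsd_threshold))
  merit_b <- stage("merit", merit_report(table_b, cfg$rsd_threshold))
  paired <- stage("merit", compare_common_merit(merit_a, merit_b, matches))

  level2 <- list()
  for (ct in cfg$contrasts) {
    contrast <- stage("discriminate", contrast_from_design(design, ct$factor, ct$level))
    res_a <- stage("discriminate", discriminate(table_a, contrast, cfg$n_components,
                                                cfg$folds, cfg$seed))
    res_b <- stage("discriminate", discriminate(table_b, contrast, cfg$n_components,
                                                cfg$folds, cfg$seed))
    level2[[contrast$name]] <- list(
      contrast = contrast,
      ber_a = res_a$cv$ber, ber_b = res_b$cv$ber,
      top_selectivity_a = sort(res_a$selectivity[is.finite(res_a$selectivity) &
                                                   res_a$selectivity > 1], decreasing = TRUE),
      top_selectivity_b = sort(res_b$selectivity[is.finite(res_b$selectivity) &
                                                   res_b$selectivity > 1], decreasing = TRUE),
      point_biserial_a = res_a$point_biserial, point_biserial_b = res_b$point_biserial)
  }

  level3 <- NULL
  sensory_screen <- NULL
  if (!is.null(sensory)) {
    std <- stage("sensory", standardize_sensory(sensory))
    sensory_screen <- lapply(cfg$attributes, function(att) {
      ft <- attribute_variation_test(std, att)
      c(ft, list(skewness = check_skewness(std, att)))
    })
    names(sensory_screen) <- cfg$attributes
    level3 <- lapply(cfg$attributes, function(att) {
      stage("predict", compare_platforms_level3(table_a, table_b, std, att,
                                                alpha_grid = cfg$alpha_grid,
                                                nlambda = cfg$nlambda))
    })
    names(level3) <- cfg$attributes
  }

  flags <- character(0)
  med_a <- stats::median(merit_a$per_feature$rsd, na.rm = TRUE)
  med_b <- stats::median(merit_b$per_feature$rsd, na.rm = TRUE)
  flags <- c(flags, sprintf("better median QC precision: %s (%.3f vs %.3f)",
                            if (med_a <= med_b) table_a$platform_name else table_b$platform_name,
                            min(med_a, med_b), max(med_a, med_b)))
  for (nm in names(level2)) {
    l2 <- level2[[nm]]
    flags <- c(flags, sprintf("lower CV BER for '%s': %s (%.3f vs %.3f)", nm,
                              if (l2$ber_a <= l2$ber_b) table_a$platform_name else table_b$platform_name,
                              min(l2$ber_a, l2$ber_b), max(l2$ber_a, l2$ber_b)))
  }
  if (!is.null(level3)) {
    for (nm in names(level3)) {
      l3 <- level3[[nm]]
      flags <- c(flags, sprintf("lower LOOCV MSE for '%s': %s (%.4f vs %.4f)", nm,
                                if (l3$mse_a <= l3$mse_b) table_a$platform_name else table_b$platform_name,
                                min(l3$mse_a, l3$mse_b), max(l3$mse_a, l3$mse_b)))
    }
  }

  report <- structure(list(
    platforms = c(a = table_a$platform_name, b = table_b$platform_name),
    config = cfg,
    matches = matches,
    partition_sizes = vapply(parts, length, integer(1)),
    level1 = list(merit_a = merit_a, merit_b = merit_b, common = paired),
    level2 = level2,
    sensory_screen = sensory_screen,
    level3 = level3,
    level3_skipped = is.null(level3),
    flags = flags), class = "comparison_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("== Method comparison: %s vs %s ==\n", x$platforms[["a"]], x$platforms[["b"]]))
  cat(sprintf("Common metabolites: %d (unique: %d / %d)\n",
              nrow(x$matches$pairs), x$partition_sizes[["unique_a_ids"]],
              x$partition_sizes[["unique_b_ids"]]))
  cat(sprintf("Level 1: fraction RSD < %.2f: %.2f vs %.2f; common pairs above diagonal %d, below %d\n",
              x$config$rsd_threshold,
              x$level1$merit_a$fraction_below_threshold,
              x$level1$merit_b$fraction_below_threshold,
              x$level1$common$n_above_diagonal, x$level1$common$n_below_diagonal))
  for (nm in names(x$level2)) {
    cat(sprintf("Level 2 [%s]: BER %.3f vs %.3f\n", nm,
                x$level2[[nm]]$ber_a, x$level2[[nm]]$ber_b))
  }
  if (x$level3_skipped) {
    cat("Level 3: skipped (no sensory data)\n")
  } else {
    for (nm in names(x$level3)) {
      cat(sprintf("Level 3 [%s]: MSE %.4f vs %.4f\n", nm,
                  x$level3[[nm]]$mse_a, x$level3[[nm]]$mse_b))
    }
  }
  cat("Evidence summary:\n")
  for (f in x$flags) cat("  - ", f, "\n", sep = "")
  invisible(x)
}

# serialisable numeric core of the report; every value traceable to a stage
report_numbers <- function(x) {
  out <- list(
    platforms = as.list(x$platforms),
    n_common = nrow(x$matches$pairs),
    partition_sizes = as.list(x$partition_sizes),
    level1 = list(
      median_rsd_a = stats::median(x$level1$merit_a$per_feature$rsd, na.rm = TRUE),
      median_rsd_b = stats::median(x$level1$merit_b$per_feature$rsd, na.rm = TRUE),
      fraction_below_threshold_a = x$level1$merit_a$fraction_below_threshold,
      fraction_below_threshold_b = x$level1$merit_b$fraction_below_threshold,
      common_above_diagonal = x$level1$common$n_above_diagonal,
      common_below_diagonal = x$level1$common$n_below_diagonal),
    level2 = lapply(x$level2, function(l2) list(
      n_positive = l2$contrast$n_positive, n_negative = l2$contrast$n_negative,
      ber_a = l2$ber_a, ber_b = l2$ber_b,
      n_selectivity_gt1_a = length(l2$top_selectivity_a),
      n_selectivity_gt1_b = length(l2$top_selectivity_b))),
    flags = x$flags)
  if (!x$level3_skipped) {
    out$sensory_screen <- lapply(x$sensory_screen, function(s)
      list(f_statistic = s$statistic, p_value = s$p_value, skewness = s$skewness$skewness))
    out$level3 <- lapply(x$level3, function(l3) list(
      mse_a = l3$mse_a, mse_b = l3$mse_b,
      alpha_a = l3$a$alpha, lambda_a = l3$a$lambda,
      alpha_b = l3$b$alpha, lambda_b = l3$b$lambda,
      n_selected_a = length(l3$a$selected_features),
      n_selected_b = length(l3$b$selected_features)))
  } else {
    out$level3 <- "skipped"
  }
  out
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_numbers(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$matches$pairs, file.path(dir, "matches.csv"), row.names = FALSE)
  utils::write.csv(report$level1$merit_a$per_feature, file.path(dir, "merit_a.csv"),
                   row.names = FALSE)
  utils::write.csv(report$level1$merit_b$per_feature, file.path(dir, "merit_b.csv"),
                   row.names = FALSE)
  utils::write.csv(report$level1$common$paired, file.path(dir, "merit_paired.csv"),
                   row.names = FALSE)
  if (!report$level3_skipped) {
    for (nm in names(report$level3)) {
      utils::write.csv(report$level3[[nm]]$a$pairs,
                       file.path(dir, sprintf("predictions_%s_a.csv", gsub("[^A-Za-z0-9._-]", "_", nm))),
                       row.names = FALSE)
      utils::write.csv(report$level3[[nm]]$b$pairs,
                       file.path(dir, sprintf("predictions_%s_b.csv", gsub("[^A-Za-z0-9._-]", "_", nm))),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
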