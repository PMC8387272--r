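test_that("generation is fully reproducible from the seed", {
  cfg <- list(seed = 13, n_features_a = 20, n_features_b = 25, n_common = 10,
              n_annotated_common = 5, n_annotated_unique_a = 3, n_annotated_unique_b = 3,
              design_effects = list())
  b1 <- do.call(default_study_fixture, cfg)
  b2 <- do.call(default_study_fixture, cfg)
  expect_identical(b1$table_a, b2$table_a)
  expect_identical(b1$table_b, b2$table_b)
  expect_identical(b1$sensory, b2$sensory)
  expect_identical(b1$truth, b2$truth)
  b3 <- do.call(default_study_fixture, utils::modifyList(cfg, list(seed = 14)))
  expect_false(identical(b1$table_a$intensities, b3$table_a$intensities))
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_common = 500, n_features_a = 300, n_features_b = 400),
               "n_common")
  expect_error(generator_config(n_qc_a = 1), "2 QC replicates")
  expect_error(generator_config(n_annotated_common = 200, n_common = 100), "annotation")
  expect_error(generator_config(design_effects = list(
    list(factor = "ghost", level = "x", n_common = 1, n_unique_a = 0,
         n_unique_b = 0, multiplier = 2))), "ghost")
})

test_that("noise-free spectra make the matcher recover exactly the planted pairs", {
  bnd <- default_study_fixture(seed = 15, n_features_a = 40, n_features_b = 50,
                               n_common = 20, spectrum_noise = 0, ri_jitter = 0,
                               n_annotated_common = 10, n_annotated_unique_a = 5,
                               n_annotated_unique_b = 5)
  ms <- find_common_metabolites(bnd$table_a, bnd$table_b, ri_tolerance = 2,
                                sim_threshold = 0.99)
  got <- paste(ms$pairs$feature_a, ms$pairs$feature_b)
  want <- paste(bnd$truth$common_pairs$feature_a, bnd$truth$common_pairs$feature_b)
  expect_setequal(got, want)
})

test_that("QC columns realise the configured RSD profile without bias", {
  bnd <- default_study_fixture(seed = 16, n_features_a = 500, n_features_b = 60,
                               n_common = 20, n_annotated_common = 10,
                               n_annotated_unique_a = 5, n_annotated_unique_b = 5)
  emp <- merit_report(bnd$table_a)$per_feature$rsd
  target <- bnd$truth$rsd_a
  expect_lt(abs(mean(emp - target)), 0.02)
})

test_that("matcher sensitivity degrades monotonically with spectral noise", {
  sens <- vapply(c(0, 0.1, 0.25, 0.5, 0.9), function(noise) {
    bnd <- default_study_fixture(seed = 17, n_features_a = 70, n_features_b = 80,
                                 n_common = 60, spectrum_noise = noise,
                                 n_annotated_common = 10, n_annotated_unique_a = 5,
                                 n_annotated_unique_b = 5)
    ms <- find_common_metabolites(bnd$table_a, bnd$table_b, 2, 0.65)
    truth <- paste(bnd$truth$common_pairs$feature_a, bnd$truth$common_pairs$feature_b)
    sum(paste(ms$pairs$feature_a, ms$pairs$feature_b) %in% truth) / length(truth)
  }, numeric(1))
  expect_equal(sens[1], 1)
  expect_true(all(diff(sens) <= 0))
})

test_that("without design effects the labels cannot be predicted from the features", {
  bnd <- default_study_fixture(seed = 18, n_features_a = 40, n_features_b = 40,
                               n_common = 20, design_effects = list(),
                               n_annotated_common = 10, n_annotated_unique_a = 5,
                               n_annotated_unique_b = 5)
  ct <- contrast_from_design(bnd$design, "yeast_product", "Maxagusto O-31")
  res <- cv_plsda(bnd$table_b, ct, n_components = 2, folds = 5, seed = 2)
  expect_gte(res$ber, 0.35)
})

test_that("noise-free sensory recovers the planted product effects exactly", {
  bnd <- default_study_fixture(
    seed = 19, n_features_a = 30, n_features_b = 40, n_common = 15,
    n_annotated_common = 5, n_annotated_unique_a = 3, n_annotated_unique_b = 3,
    sensory_effects = list(intensity.od = list(n_common = 3, n_unique_a = 0,
                                               n_unique_b = 3, noise_sd = 0)),
    panellist_level_sd = 0, panellist_scale_sdlog = 0)
  std <- suppressWarnings(standardize_sensory(bnd$sensory))
  pm <- product_means(std, "intensity.od", products = bnd$design$product_id)
  truth <- bnd$truth$sensory_effects$intensity.od$product_effect
  expect_equal(stats::cor(pm, truth), 1, tolerance = 1e-9)
})

test_that("the default fixture has the study's shape", {
  bnd <- shared_bundle()
  expect_equal(bnd$table_a$platform_name, "platform_a")
  expect_equal(sum(bnd$table_a$samples$role == "product"), 27L)
  expect_equal(sum(bnd$table_a$samples$role == "qc"), 5L)
  expect_equal(sum(bnd$table_b$samples$role == "qc"), 4L)
  expect_equal(length(unique(bnd$sensory$panellist_id)), 14L)
  expect_setequal(unique(bnd$sensory$attribute), c("intensity.od", "umami.fl"))
  expect_true(all(bnd$sensory$intensity >= 0 & bnd$sensory$intensity <= 100))
  # ground truth consistent with the emitted tables
  expect_true(all(bnd$truth$common_pairs$feature_a %in% names(bnd$table_a$features)))
  expect_true(all(bnd$truth$common_pairs$feature_b %in% names(bnd$table_b$features)))
})

test_that("the bundle writer emits the five standard files plus ground truth", {
  bnd <- default_study_fixture(seed = 20, n_features_a = 10, n_features_b = 12,
                               n_common = 5, n_annotated_common = 3,
                               n_annotated_unique_a = 2, n_annotated_unique_b = 2,
                               design_effects = list())
  dir <- withr::local_tempdir()
  write_bundle(bnd, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "a/intensities.csv", "a/spectra.msp", "a/samples.csv",
    "b/intensities.csv", "b/spectra.msp", "b/samples.csv",
    "design.csv", "sensory.csv", "truth.json")))))
  d2 <- read_design_table(file.path(dir, "design.csv"))
  expect_equal(as.data.frame(d2), as.data.frame(bnd$design), ignore_attr = TRUE)
  s2 <- read_sensory_table(file.path(dir, "sensory.csv"))
  expect_equal(s2$intensity, bnd$sensory$intensity, tolerance = 1e-12)
})
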