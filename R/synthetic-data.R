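#' The 27-product tomato-soup compositional design
#'
#' The encoded study design: 27 soups varying tomato dosage, oil type and
#' dosage, yeast-derived flavour product and yeast dosage ("-" marks no yeast
#' added). Seven soups contain yeast product Maxagusto O-31; nineteen use
#' olive oil and eight corn oil. The products pooled into the QC mix are
#' recorded in the `qc_products` attribute.
#'
#' @return A [design_table()] with attribute `qc_products`.
#' @export
soup_design <- function() {
  df <- data.frame(
    product_id = sprintf("P%02d", 1:27),
    tomato_dosage = c(rep("Low", 15), rep("High", 4), rep("Low", 4), rep("High", 4)),
    oil_type = c(rep("Olive", 19), rep("Corn", 8)),
    oil_dosage = c(rep("High", 15), rep("Low", 4), rep("High", 4), rep("Low", 4)),
    yeast_product = c("-", "Maxarome", "Maxarome", "Maxavor", "Maxavor",
                      "Maxagusto S-99", "Maxagusto S-99", "Maxagusto S-99", "Maxagusto S-99",
                      "Maxagusto O-31", "Maxagusto O-31", "Maxagusto O-31", "Maxagusto O-31",
                      "Maxagusto G-28", "Maxagusto G-28",
                      "-", "Maxagusto S-99", "Maxagusto O-31", "Maxagusto G-28",
                      "-", "Maxagusto S-99", "Maxagusto O-31", "Maxagusto G-28",
                      "-", "Maxagusto S-99", "Maxagusto O-31", "Maxagusto G-28"),
    yeast_dosage = c("-", "Low", "High", "Low", "High",
                     "Low", "Low", "High", "High",
                     "Low", "Low", "High", "High",
                     "Low", "High",
                     "-", "High", "High", "High",
                     "-", "High", "High", "High",
                     "-", "High", "High", "High"),
    stringsAsFactors = FALSE)
  d <- design_table(df)
  attr(d, "qc_products") <- sprintf("P%02d", c(7, 11, 17, 18, 19, 25, 26, 27))
  d
}

#' Configuration for the two-platform synthetic data generator
#'
#' Defaults mirror the dimensions of the motivating tomato-soup study: 27
#' products, 14 panellists, 331 features on platform A (SPME-like) and 482 on
#' platform B (SBSE-like) of which 130 are common, 5 and 4 QC injections, and
#' RSD distributions centred lower for A (median 0.10) than for B (median
#' 0.25) so A has the better precision while B carries more (and more
#' design-relevant) unique metabolites.
#'
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param design a [design_table()] (default [soup_design()]).
#' @param n_panellists sensory panel size.
#' @param n_sessions assessments per (panellist, product).
#' @param n_features_a,n_features_b,n_common platform feature counts and the
#'   number of planted common metabolites.
#' @param n_qc_a,n_qc_b QC replicate counts.
#' @param rsd_profile_a,rsd_profile_b `list(median, sdlog)` log-normal RSD
#'   distribution per platform (truncated to \[0.01, 1.5\]).
#' @param spectrum_noise sd of the multiplicative log-normal peak-intensity
#'   perturbation applied independently per platform to each common
#'   metabolite's base spectrum; also scales the low-intensity peak
#'   drop-out/drop-in rates. 0 gives identical spectra on both platforms.
#' @param ri_jitter sd of the per-platform retention-index jitter (clamped to
#'   +/- 0.9 RI units so a tolerance of 2 always covers true pairs).
#' @param bio_sd sd of the shared log-normal product-to-product abundance
#'   noise (the biology both platforms see).
#' @param design_effects list of effects, each
#'   `list(factor, level, n_common, n_unique_a, n_unique_b, multiplier)`:
#'   products at that factor level have the member metabolites' abundance
#'   multiplied by `multiplier`.
#' @param sensory_effects named list per attribute:
#'   `list(n_common, n_unique_a, n_unique_b, noise_sd)`; the attribute is a
#'   weighted sum of the member metabolites' sqrt-scale abundance profiles
#'   (standardised over products, scaled by `sensory_scale`) plus panel
#'   noise. Attributes with no members are pure noise (the umami-like case).
#' @param sensory_scale score points per unit of standardised signal.
#' @param panellist_level_sd,panellist_scale_sdlog distributions of the
#'   panellist level offset and scale factor.
#' @param n_annotated_common,n_annotated_unique_a,n_annotated_unique_b how
#'   many common/unique metabolites carry (shared/platform-only) annotation
#'   names, the calibration ground truth.
#' @param qc_products product ids pooled into the QC mix (default: the
#'   design's `qc_products` attribute, else all products).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             design = soup_design(),
                             n_panellists = 14,
                             n_sessions = 1,
                             n_features_a = 331, n_features_b = 482,
                             n_common = 130,
                             n_qc_a = 5, n_qc_b = 4,
                             rsd_profile_a = list(median = 0.10, sdlog = 0.5),
                             rsd_profile_b = list(median = 0.25, sdlog = 0.5),
                             spectrum_noise = 0.15,
                             ri_jitter = 0.5,
                             bio_sd = 0.3,
                             design_effects = NULL,
                             sensory_effects = NULL,
                             sensory_scale = 12,
                             panellist_level_sd = 8,
                             panellist_scale_sdlog = 0.2,
                             n_annotated_common = 61,
                             n_annotated_unique_a = 39,
                             n_annotated_unique_b = 49,
                             qc_products = NULL) {
  stopifnot(inherits(design, "design_table"))
  if (n_common > min(n_features_a, n_features_b)) {
    stop("n_common cannot exceed the smaller platform's feature count", call. = FALSE)
  }
  counts <- c(n_panellists, n_sessions, n_features_a, n_features_b, n_common,
              n_qc_a, n_qc_b)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (n_qc_a < 2 || n_qc_b < 2) stop("need >= 2 QC replicates per platform for RSDs", call. = FALSE)
  if (is.null(design_effects)) {
    design_effects <- list(
      list(factor = "yeast_product", level = "Maxagusto O-31",
           n_common = 6, n_unique_a = 2, n_unique_b = 8, multiplier = 3),
      list(factor = "oil_type", level = "Olive",
           n_common = 4, n_unique_a = 2, n_unique_b = 2, multiplier = 2),
      list(factor = "tomato_dosage", level = "High",
           n_common = 5, n_unique_a = 3, n_unique_b = 3, multiplier = 1.8))
  }
  if (is.null(sensory_effects)) {
    sensory_effects <- list(
      intensity.od = list(n_common = 4, n_unique_a = 0, n_unique_b = 4, noise_sd = 5),
      umami.fl = list(n_common = 0, n_unique_a = 0, n_unique_b = 0, noise_sd = 8))
  }
  for (eff in design_effects) {
    if (!eff$factor %in% names(design)) {
      stop(sprintf("design effect factor '%s' not in design", eff$factor), call. = FALSE)
    }
    if (!eff$level %in% design[[eff$factor]]) {
      stop(sprintf("design effect level '%s' absent from factor '%s'", eff$level, eff$factor),
           call. = FALSE)
    }
  }
  if (n_annotated_common > n_common ||
      n_annotated_unique_a > n_features_a - n_common ||
      n_annotated_unique_b > n_features_b - n_common) {
    stop("annotation counts exceed the available metabolites", call. = FALSE)
  }
  if (is.null(qc_products)) qc_products <- attr(design, "qc_products") %||% design$product_id
  structure(list(seed = seed, design = design, n_panellists = n_panellists,
                 n_sessions = n_sessions,
                 n_features_a = n_features_a, n_features_b = n_features_b,
                 n_common = n_common, n_qc_a = n_qc_a, n_qc_b = n_qc_b,
                 rsd_profile_a = rsd_profile_a, rsd_profile_b = rsd_profile_b,
                 spectrum_noise = spectrum_noise, ri_jitter = ri_jitter,
                 bio_sd = bio_sd, design_effects = design_effects,
                 sensory_effects = sensory_effects, sensory_scale = sensory_scale,
                 panellist_level_sd = panellist_level_sd,
                 panellist_scale_sdlog = panellist_scale_sdlog,
                 n_annotated_common = n_annotated_common,
                 n_annotated_unique_a = n_annotated_unique_a,
                 n_annotated_unique_b = n_annotated_unique_b,
                 qc_products = qc_products),
            class = "generator_config")
}

# random EI-like base spectrum on integer m/z 40-300, base peak scaled to 999
random_spectrum <- function() {
  n <- 5L + stats::rpois(1, 10)
  mz <- sample(40:300, n)
  inten <- stats::rlnorm(n, log(50), 1.2)
  inten <- inten / max(inten) * 999
  mass_spectrum(mz, inten)
}

# platform-specific perturbation: multiplicative log-normal peak noise plus
# drop-out of minor peaks and drop-in of spurious low-intensity peaks; the
# base peak always survives so the spectrum stays valid
perturb_spectrum <- function(spec, noise) {
  if (noise <= 0) return(spec)
  inten <- spec$intensity * exp(stats::rnorm(length(spec$mz), 0, noise))
  keep <- rep(TRUE, length(inten))
  minor <- inten < 0.1 * max(inten)
  keep[minor] <- stats::runif(sum(minor)) > min(0.5, 2 * noise)
  keep[which.max(inten)] <- TRUE
  mz <- spec$mz[keep]; inten <- inten[keep]
  n_in <- stats::rpois(1, 10 * noise)
  free <- setdiff(40:300, round(mz))
  if (n_in > 0 && length(free)) {
    n_in <- min(n_in, length(free))
    mz <- c(mz, sample(free, n_in))
    inten <- c(inten, stats::runif(n_in, 1, 0.05 * max(inten)))
  }
  mass_spectrum(mz, inten)
}

#' Generate a linked two-platform synthetic study with ground truth
#'
#' Emulates the statistical structure the three comparison levels assume.
#' Common metabolites share a latent abundance profile (baseline x design
#' multipliers x shared log-normal biology) observed by both platforms
#' through platform response factors and multiplicative measurement noise;
#' their spectra are independently perturbed copies of one base spectrum and
#' their retention indices jittered copies of one base RI. QC intensities are
#' drawn around the QC-mix mean with each feature's configured RSD. Sensory
#' scores are a weighted linear readout of member metabolites' standardised
#' sqrt-abundance profiles, distorted per panellist by level and scale
#' effects, plus noise, clipped to the 0-100 scale.
#'
#' @param config a [generator_config()].
#' @return A list (the "bundle") with `table_a`, `table_b` ([feature_table()]),
#'   `design`, `sensory`, and `truth` (planted common pairs, per-feature true
#'   RSDs, design-effect and sensory-effect memberships, true product
#'   effects, panellist biases).
#' @export
generate_two_platform_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  design <- cfg$design
  products <- design$product_id
  n_prod <- length(products)

  # ---- latent metabolites -------------------------------------------------
  n_ua <- cfg$n_features_a - cfg$n_common
  n_ub <- cfg$n_features_b - cfg$n_common
  lat_common <- sprintf("M_C%03d", seq_len(cfg$n_common))
  lat_ua <- if (n_ua) sprintf("M_A%03d", seq_len(n_ua)) else character(0)
  lat_ub <- if (n_ub) sprintf("M_B%03d", seq_len(n_ub)) else character(0)
  lat_all <- c(lat_common, lat_ua, lat_ub)
  n_lat <- length(lat_all)

  baseline <- stats::setNames(stats::rlnorm(n_lat, log(1e5), 1), lat_all)
  base_ri <- stats::setNames(stats::runif(n_lat, 800, 2400), lat_all)
  base_spec <- stats::setNames(lapply(seq_len(n_lat), function(i) random_spectrum()), lat_all)

  # ---- design effects -----------------------------------------------------
  mult <- matrix(1, n_lat, n_prod, dimnames = list(lat_all, products))
  pool <- list(common = lat_common, ua = lat_ua, ub = lat_ub)  # unassigned
  effects_truth <- list()
  for (eff in cfg$design_effects) {
    take <- function(kind, k) {
      if (k > length(pool[[kind]])) stop("not enough unassigned metabolites for design effects",
                                         call. = FALSE)
      picked <- if (k > 0) sample(pool[[kind]], k) else character(0)
      pool[[kind]] <<- setdiff(pool[[kind]], picked)
      picked
    }
    members <- c(take("common", eff$n_common), take("ua", eff$n_unique_a),
                 take("ub", eff$n_unique_b))
    hit <- design[[eff$factor]] == eff$level
    mult[members, hit] <- mult[members, hit] * eff$multiplier
    effects_truth[[paste(eff$factor, eff$level, sep = ":")]] <-
      list(factor = eff$factor, level = eff$level, multiplier = eff$multiplier,
           metabolites = members)
  }

  # shared biology: true per-product abundance, identical for both platforms
  bio <- matrix(exp(stats::rnorm(n_lat * n_prod, 0, cfg$bio_sd)), n_lat, n_prod)
  abundance <- baseline * mult * bio
  dimnames(abundance) <- list(lat_all, products)

  # ---- sensory truth (from sqrt-scale abundance profiles) -----------------
  sens_truth <- list()
  for (attr_name in names(cfg$sensory_effects)) {
    se <- cfg$sensory_effects[[attr_name]]
    members <- c(if (se$n_common > 0) sample(lat_common, se$n_common),
                 if (se$n_unique_a > 0) sample(lat_ua, se$n_unique_a),
                 if (se$n_unique_b > 0) sample(lat_ub, se$n_unique_b))
    if (length(members)) {
      sig <- colSums(sqrt(abundance[members, , drop = FALSE]))
      z <- as.numeric(scale(sig))
    } else {
      z <- rep(0, n_prod)
    }
    sens_truth[[attr_name]] <- list(metabolites = members %||% character(0),
                                    noise_sd = se$noise_sd,
                                    product_effect = stats::setNames(z, products))
  }

  # ---- platform tables ----------------------------------------------------
  build_platform <- function(platform_name, prefix, lat_ids, n_qc, rsd_profile) {
    nf <- length(lat_ids)
    ord <- sample(nf)  # hide the common/unique structure in the id order
    lat_ids <- lat_ids[ord]
    fids <- sprintf("%s_F%03d", prefix, seq_len(nf))
    rsd <- stats::rlnorm(nf, log(rsd_profile$median), rsd_profile$sdlog)
    rsd <- pmin(pmax(rsd, 0.01), 1.5)
    resp <- stats::rlnorm(nf, 0, 0.3)  # platform response factor
    ri_j <- if (cfg$ri_jitter > 0) {
      pmin(pmax(stats::rnorm(nf, 0, cfg$ri_jitter), -0.9), 0.9)
    } else rep(0, nf)

    sigma <- sqrt(log(1 + rsd^2))
    prod_m <- abundance[lat_ids, , drop = FALSE] * resp *
      matrix(exp(stats::rnorm(nf * n_prod, 0, sigma)), nf, n_prod)
    qc_mean <- rowMeans(abundance[lat_ids, cfg$qc_products, drop = FALSE]) * resp
    qc_m <- qc_mean * matrix(exp(stats::rnorm(nf * n_qc, 0, sigma) - sigma^2 / 2), nf, n_qc)
    blank <- matrix(stats::rlnorm(nf, log(10), 0.5), nf, 1)

    m <- cbind(prod_m, qc_m, blank)
    sample_ids <- c(products, sprintf("QC%d", seq_len(n_qc)), "BLANK1")
    dimnames(m) <- list(fids, sample_ids)
    samples <- data.frame(sample_id = sample_ids,
                          role = c(rep("product", n_prod), rep("qc", n_qc), "blank"),
                          product_id = c(products, rep(NA_character_, n_qc + 1L)),
                          stringsAsFactors = FALSE)

    feats <- lapply(seq_len(nf), function(i) {
      feature(fids[i], base_ri[lat_ids[i]] + ri_j[i],
              perturb_spectrum(base_spec[[lat_ids[i]]], cfg$spectrum_noise))
    })
    list(table = feature_table(platform_name, feats, samples, m),
         latent = stats::setNames(lat_ids, fids),
         rsd = stats::setNames(rsd, fids))
  }

  pa <- build_platform("platform_a", "A", c(lat_common, lat_ua), cfg$n_qc_a, cfg$rsd_profile_a)
  pb <- build_platform("platform_b", "B", c(lat_common, lat_ub), cfg$n_qc_b, cfg$rsd_profile_b)

  # ---- annotations (calibration ground truth) -----------------------------
  ann_common <- if (cfg$n_annotated_common > 0) sample(lat_common, cfg$n_annotated_common) else character(0)
  ann_ua <- if (cfg$n_annotated_unique_a > 0) sample(lat_ua, cfg$n_annotated_unique_a) else character(0)
  ann_ub <- if (cfg$n_annotated_unique_b > 0) sample(lat_ub, cfg$n_annotated_unique_b) else character(0)
  annotate <- function(p, lat_set) {
    hits <- names(p$latent)[p$latent %in% lat_set]
    for (fid in hits) {
      p$table$features[[fid]]$annotation <- paste0("cmpd ", p$latent[[fid]])
    }
    p
  }
  pa <- annotate(annotate(pa, ann_common), ann_ua)
  pb <- annotate(annotate(pb, ann_common), ann_ub)

  # ---- sensory table ------------------------------------------------------
  panellists <- sprintf("J%02d", seq_len(cfg$n_panellists))
  level_off <- stats::setNames(stats::rnorm(cfg$n_panellists, 0, cfg$panellist_level_sd), panellists)
  scale_fac <- stats::setNames(stats::rlnorm(cfg$n_panellists, 0, cfg$panellist_scale_sdlog), panellists)
  rec <- list()
  for (attr_name in names(sens_truth)) {
    target <- 50 + cfg$sensory_scale * sens_truth[[attr_name]]$product_effect
    nsd <- sens_truth[[attr_name]]$noise_sd
    for (s in seq_len(cfg$n_sessions)) {
      for (i in panellists) {
        y <- 50 + level_off[i] + scale_fac[i] * (target - 50) +
          stats::rnorm(n_prod, 0, nsd)
        rec[[length(rec) + 1L]] <- data.frame(
          panellist_id = i, product_id = products, attribute = attr_name,
          session = s, intensity = pmin(pmax(y, 0), 100), stringsAsFactors = FALSE)
      }
    }
  }
  sensory <- sensory_table(do.call(rbind, rec))

  # ---- ground truth -------------------------------------------------------
  inv_a <- stats::setNames(names(pa$latent), pa$latent)  # latent -> feature id
  inv_b <- stats::setNames(names(pb$latent), pb$latent)
  common_pairs <- data.frame(feature_a = unname(inv_a[lat_common]),
                             feature_b = unname(inv_b[lat_common]),
                             latent = lat_common, stringsAsFactors = FALSE)
  effects_truth <- lapply(effects_truth, function(e) {
    e$features_a <- unname(inv_a[intersect(e$metabolites, names(inv_a))])
    e$features_b <- unname(inv_b[intersect(e$metabolites, names(inv_b))])
    e
  })
  sens_truth <- lapply(sens_truth, function(e) {
    e$features_a <- unname(inv_a[intersect(e$metabolites, names(inv_a))])
    e$features_b <- unname(inv_b[intersect(e$metabolites, names(inv_b))])
    e
  })

  list(table_a = pa$table, table_b = pb$table, design = design, sensory = sensory,
       truth = list(common_pairs = common_pairs,
                    rsd_a = pa$rsd, rsd_b = pb$rsd,
                    latent_a = pa$latent, latent_b = pb$latent,
                    design_effects = effects_truth,
                    sensory_effects = sens_truth,
                    annotated_common = unname(ann_common),
                    panellist_level = level_off, panellist_scale = scale_fac,
                    config = cfg[setdiff(names(cfg), "design")]))
}

#' Default synthetic study fixture
#'
#' Generates the bundle at the study's dimensions: the encoded 27-soup
#' design (7-product O-31 subset, 19/8 olive/corn split), 14 panellists,
#' 331/482 features with 130 commons, and 5/4 QC injections.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [generator_config()].
#' @return A bundle as from [generate_two_platform_data()].
#' @export
default_study_fixture <- function(seed = 1, ...) {
  generate_two_platform_data(generator_config(seed = seed, ...))
}
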