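#' Region metadata mimicking a FreeSurfer-style parcellation
#'
#' Builds a feature dictionary with Desikan-Killiany-like cortical labels
#' (thickness + volume per hemisphere) and aseg-like subcortical volume
#' labels, so that real `aparcstats2table`/`asegstats2table` exports can be
#' substituted for simulated tables.  The default of 183 features matches the
#' parcellation used throughout the package (2 x 34 cortical regions as both
#' thickness and volume = 136, plus 47 subcortical/global volumes).
#'
#' @param n_regions total number of features (default 183). Values other than
#'   183 yield generic `region_###` labels (half thickness, half volume).
#' @return data.frame with columns `feature`, `measure` ("thickness" or
#'   "volume"), `hemisphere` ("lh", "rh" or "bilateral"), `region`.
#' @export
region_metadata <- function(n_regions = 183L) {
  dk <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
          "cuneus", "entorhinal", "fusiform", "inferiorparietal",
          "inferiortemporal", "isthmuscingulate", "lateraloccipital",
          "lateralorbitofrontal", "lingual", "medialorbitofrontal",
          "middletemporal", "paracentral", "parahippocampal",
          "parsopercularis", "parsorbitalis", "parstriangularis",
          "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
          "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
          "superiorfrontal", "superiorparietal", "superiortemporal",
          "supramarginal", "temporalpole", "transversetemporal", "insula",
          "frontalpole")
  aseg_bilateral <- c("Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
                      "Hippocampus", "Amygdala", "Accumbens-area",
                      "VentralDC", "Lateral-Ventricle", "Inf-Lat-Vent",
                      "Cerebellum-White-Matter", "Cerebellum-Cortex",
                      "choroid-plexus", "Cerebral-White-Matter",
                      "vessel", "Thalamus-nuclei")  # 16 x 2 = 32
  aseg_midline <- c("Brain-Stem", "CSF", "3rd-Ventricle", "4th-Ventricle",
                    "5th-Ventricle", "CC_Posterior", "CC_Mid_Posterior",
                    "CC_Central", "CC_Mid_Anterior", "CC_Anterior",
                    "WM-hypointensities", "Optic-Chiasm",
                    "SubCortGrayVol", "TotalGrayVol", "SupraTentorialVol")
  if (identical(as.integer(n_regions), 183L)) {
    cort <- expand.grid(hemisphere = c("lh", "rh"), region = dk,
                        measure = c("thickness", "volume"),
                        stringsAsFactors = FALSE)
    sub1 <- expand.grid(hemisphere = c("Left", "Right"),
                        region = aseg_bilateral, stringsAsFactors = FALSE)
    meta <- rbind(
      data.frame(feature = paste(cort$hemisphere, cort$region, cort$measure,
                                 sep = "_"),
                 measure = cort$measure, hemisphere = cort$hemisphere,
                 region = cort$region, stringsAsFactors = FALSE),
      data.frame(feature = paste(sub1$hemisphere, sub1$region, sep = "-"),
                 measure = "volume",
                 hemisphere = ifelse(sub1$hemisphere == "Left", "lh", "rh"),
                 region = sub1$region, stringsAsFactors = FALSE),
      data.frame(feature = aseg_midline, measure = "volume",
                 hemisphere = "bilateral", region = aseg_midline,
                 stringsAsFactors = FALSE))
    stopifnot(nrow(meta) == 183L)
  } else {
    n_regions <- as.integer(n_regions)
    stopifnot(n_regions >= 2)
    n_th <- n_regions %/% 2L
    meta <- data.frame(
      feature = sprintf("region_%03d_%s", seq_len(n_regions),
                        rep(c("thickness", "volume"),
                            c(n_th, n_regions - n_th))),
      measure = rep(c("thickness", "volume"), c(n_th, n_regions - n_th)),
      hemisphere = "bilateral",
      region = sprintf("region_%03d", seq_len(n_regions)),
      stringsAsFactors = FALSE)
  }
  rownames(meta) <- NULL
  meta
}

#' Simulation configuration for the synthetic multi-cohort generator
#'
#' The defaults encode the cohort structure the generator is meant to
#' emulate: a large training cohort aged 44-81 with ~52% females, smaller
#' evaluation cohorts, a latent per-subject aging acceleration ("delta", in
#' years) with SD `sigma_delta`, APOE-genotype shifts of delta, biomarkers
#' coupled to delta and to a shared latent pathology score at configurable
#' standardized effect sizes, and a follow-up visit after ~3 years.
#'
#' @param n_subjects named integer vector: subjects per cohort.
#' @param age_range numeric length-2, years (default `c(44, 81)`).
#' @param fraction_female proportion of females in `[0, 1]`.
#' @param n_sites number of scanning sites.
#' @param n_regions number of ROI features (default 183).
#' @param sigma_delta SD of the latent aging acceleration delta, years.
#' @param effects named list of standardized effects: for each biomarker, a
#'   length-2 numeric `c(delta = ..., pathology = ...)` giving the loading of
#'   delta (scaled by its SD) and of the latent pathology score on the
#'   biomarker's standardized (log-)scale.  Negative loadings for CSF
#'   amyloid-beta encode that *lower* values are abnormal.
#' @param apoe_freq named numeric, genotype frequencies (sum to 1).
#' @param apoe_delta_shift named numeric, additive shift of delta (years) per
#'   genotype.
#' @param apoe_pathology_shift named numeric, additive shift of the latent
#'   pathology score per genotype.
#' @param noise_sd_thickness residual SD of thickness features, mm.
#' @param noise_sd_volume_frac residual SD of volume features, as a fraction
#'   of the region's base volume.
#' @param shared_noise_sd SD of a per-subject global noise term added to all
#'   features (on each feature's own scale); crude spatial covariance.
#' @param sex_age_interaction_sd SD of the region-level sex-by-age slope
#'   difference, as a fraction of the main age slope.
#' @param follow_up_interval years between visit 1 and visit 2.
#' @param followup_accel `g`: per-year trajectory multiplier `1 + g * delta`
#'   at follow-up.
#' @param seed integer seed; regeneration with the same seed is identical.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_subjects = c(TRAIN = 2000L, TEST = 500L),
                       age_range = c(44, 81),
                       fraction_female = 0.52,
                       n_sites = 3L,
                       n_regions = 183L,
                       sigma_delta = 5,
                       effects = list(
                         csf_ab42   = c(delta = -0.25, pathology = -0.45),
                         csf_ptau   = c(delta = 0.25, pathology = 0.45),
                         csf_nfl    = c(delta = 0.25, pathology = 0.15),
                         plasma_nfl = c(delta = 0.30, pathology = 0.15),
                         centiloid  = c(delta = 0.25, pathology = 0.50),
                         wmh        = c(delta = 0.30, pathology = 0.10)),
                       apoe_freq = c(e22 = 0.01, e23 = 0.11, e33 = 0.58,
                                     e24 = 0.02, e34 = 0.25, e44 = 0.03),
                       apoe_delta_shift = c(e22 = -0.3, e23 = -0.3, e33 = 0,
                                            e24 = 0.4, e34 = 0.4, e44 = 0.8),
                       apoe_pathology_shift = c(e22 = -0.3, e23 = -0.3,
                                                e33 = 0, e24 = 0.5,
                                                e34 = 0.5, e44 = 1.0),
                       noise_sd_thickness = 0.10,
                       noise_sd_volume_frac = 0.05,
                       shared_noise_sd = 0.02,
                       sex_age_interaction_sd = 0.15,
                       follow_up_interval = 3,
                       followup_accel = 0.1,
                       seed = 1L) {
  n_subjects <- stats::setNames(as.integer(n_subjects), names(n_subjects))
  if (is.null(names(n_subjects)))
    names(n_subjects) <- paste0("COHORT", seq_along(n_subjects))
  stopifnot(all(n_subjects > 0),
            length(age_range) == 2, age_range[1] < age_range[2],
            fraction_female >= 0, fraction_female <= 1,
            n_sites >= 1, n_regions >= 2, sigma_delta >= 0,
            noise_sd_thickness >= 0, noise_sd_volume_frac >= 0,
            shared_noise_sd >= 0, follow_up_interval > 0,
            abs(sum(apoe_freq) - 1) < 1e-8)
  for (m in names(effects)) {
    e <- effects[[m]]
    if (length(e) != 2 || anyNA(e))
      stop("effect map entry for '", m, "' must be c(delta=, pathology=)")
    if (sum(e^2) > 1)
      stop("effect map entry for '", m, "' has delta^2 + pathology^2 > 1")
  }
  if (length(effects) > 0) rm(m, e)
  structure(as.list(environment()), class = "sim_config")
}

# internal: per-region generating coefficients, drawn once per config seed
.draw_region_coefs <- function(cfg, meta) {
  p <- nrow(meta)
  is_th <- meta$measure == "thickness"
  # regions that enlarge with age (ventricles, CSF spaces, WMH)
  grows <- grepl("Vent|CSF|hypoint|plexus", meta$region, ignore.case = TRUE)
  base <- ifelse(is_th, stats::runif(p, 2.0, 3.2),
                 exp(stats::runif(p, log(500), log(20000))))
  slope_age <- ifelse(is_th,
                      -stats::runif(p, 0.003, 0.012),
                      ifelse(grows, 1, -1) * base *
                        stats::runif(p, 0.002, 0.006))
  sex_main <- ifelse(is_th, stats::rnorm(p, 0, 0.03),
                     base * stats::rnorm(p, 0, 0.01))
  sex_age <- slope_age * stats::rnorm(p, 0, cfg$sex_age_interaction_sd)
  tiv_coef <- ifelse(is_th, 0, base / 1450)  # per-cm3 TIV scaling, volumes
  site_eff <- matrix(stats::rnorm(cfg$n_sites * p, 0,
                                  ifelse(is_th, 0.02, 0.01) *
                                    rep(ifelse(is_th, 1, base),
                                        each = cfg$n_sites)),
                     nrow = cfg$n_sites)
  noise_sd <- ifelse(is_th, cfg$noise_sd_thickness,
                     base * cfg$noise_sd_volume_frac)
  list(base = base, slope_age = slope_age, sex_main = sex_main,
       sex_age = sex_age, tiv_coef = tiv_coef, site_eff = site_eff,
       noise_sd = noise_sd)
}

# internal: biomarker location/scale on the generating (log or raw) scale
.biomarker_scales <- function() {
  list(csf_ab42   = list(log = TRUE,  meanlog = log(1200), sdlog = 0.45),
       csf_ptau   = list(log = TRUE,  meanlog = log(16),   sdlog = 0.40),
       csf_nfl    = list(log = TRUE,  meanlog = log(85),   sdlog = 0.33),
       plasma_nfl = list(log = TRUE,  meanlog = log(10.5), sdlog = 0.33),
       centiloid  = list(log = FALSE, mean = 13.5, sd = 28),
       wmh        = list(log = TRUE,  meanlog = log(4000), sdlog = 0.80))
}

#' Generate a synthetic multi-cohort dataset with known ground truth
#'
#' Every ROI feature is generated as
#' `x = a_r + b_r (age + delta) + c_r sex + d_r (age + delta) sex +
#'  s_site,r + k_r TIV + shared + noise` (the TIV term only for volumes),
#' where `delta` is the subject's latent aging acceleration.  Biomarkers are
#' generated on a standardized (log) scale as a linear combination of
#' `delta / sigma_delta`, a latent pathology score, and independent noise,
#' then mapped to natural units; NfL and WMH (and CSF amyloid/p-tau) are
#' log-normal.  TIV is sex-dependent (males larger).
#'
#' @param config a [sim_config()].
#' @return list with components `cohort` (demographics data.frame),
#'   `features` (subjects x regions matrix, `feature_meta` attribute),
#'   `biomarkers` (data.frame of biomarker values in natural units),
#'   `ground_truth` (list: per-subject `delta`, `pathology`, `site`, `tiv`,
#'   and all generating coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    meta <- region_metadata(cfg$n_regions)
    coefs <- .draw_region_coefs(cfg, meta)
    n <- sum(cfg$n_subjects)
    cohort_lab <- rep(names(cfg$n_subjects), cfg$n_subjects)
    id <- sprintf("sub-%05d", seq_len(n))

    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- stats::rbinom(n, 1L, cfg$fraction_female)  # 1 = female
    site <- sample.int(cfg$n_sites, n, replace = TRUE)
    tiv <- ifelse(sex == 1L, stats::rnorm(n, 1350, 120),
                  stats::rnorm(n, 1550, 130))  # cm^3
    apoe <- sample(names(cfg$apoe_freq), n, replace = TRUE,
                   prob = cfg$apoe_freq)
    delta <- stats::rnorm(n, 0, cfg$sigma_delta) +
      cfg$apoe_delta_shift[apoe]
    pathology <- stats::rnorm(n, 0, 1) + cfg$apoe_pathology_shift[apoe]
    diagnosis <- ifelse(pathology > stats::qnorm(0.85), "MCI", "CU")

    eff_age <- age + delta
    p <- nrow(meta)
    shared <- stats::rnorm(n, 0, cfg$shared_noise_sd)
    X <- matrix(0, n, p, dimnames = list(id, meta$feature))
    is_vol <- meta$measure == "volume"
    for (r in seq_len(p)) {
      mu <- coefs$base[r] + coefs$slope_age[r] * eff_age +
        coefs$sex_main[r] * sex + coefs$sex_age[r] * eff_age * sex +
        coefs$site_eff[site, r]
      if (is_vol[r]) mu <- mu + coefs$tiv_coef[r] * tiv
      scale_r <- if (is_vol[r]) coefs$base[r] / 2500 else 1
      X[, r] <- mu + shared * scale_r +
        stats::rnorm(n, 0, coefs$noise_sd[r])
    }
    attr(X, "feature_meta") <- meta
    attr(X, "state") <- "raw"

    scales <- .biomarker_scales()
    zdelta <- if (cfg$sigma_delta > 0) delta / cfg$sigma_delta else
      delta * 0
    biom <- data.frame(subject_id = id, stringsAsFactors = FALSE)
    bcoef <- list()
    for (m in names(cfg$effects)) {
      e <- cfg$effects[[m]]
      resid_sd <- sqrt(max(0, 1 - sum(e^2)))
      z <- e[["delta"]] * zdelta + e[["pathology"]] * pathology +
        stats::rnorm(n, 0, resid_sd)
      # biomarkers outside the built-in panel stay on the standardized scale
      sc <- scales[[m]] %||% list(log = FALSE, mean = 0, sd = 1)
      biom[[m]] <- if (sc$log) exp(sc$meanlog + sc$sdlog * z) else
        sc$mean + sc$sd * z
      bcoef[[m]] <- c(e, resid_sd = resid_sd)
    }

    cohort <- data.frame(
      subject_id = id, cohort = cohort_lab, age = age,
      sex = ifelse(sex == 1L, "female", "male"), site = paste0("site", site),
      tiv = tiv, apoe = apoe, diagnosis = diagnosis,
      stringsAsFactors = FALSE)

    list(cohort = cohort, features = X, biomarkers = biom,
         ground_truth = list(
           subject_id = id, delta = as.numeric(delta),
           pathology = as.numeric(pathology), sex01 = sex,
           site = site, tiv = tiv,
           region_coefs = coefs, biomarker_coefs = bcoef,
           feature_meta = meta, config = cfg))
  })
}

#' Generate a follow-up imaging visit
#'
#' Advances every subject along their own trajectory by an effective
#' interval of `interval * (1 + g * delta)` years, keeping site and TIV
#' fixed: `x2 = x1 + (b_r + d_r * sex) * interval * (1 + g * delta) + noise`.
#' Subjects with accelerated aging (positive delta) therefore thin faster
#' when `g > 0`.
#'
#' @param dataset output of [generate_cohort()].
#' @param interval years between visits (> 0); defaults to the config value.
#' @param g acceleration coupling; defaults to the config value.
#' @param noise_sd measurement noise SD for the visit-2 features, on each
#'   feature's scale (default: the config's thickness/volume noise).
#' @return visit-2 feature matrix (same shape/dimnames as visit 1).
#' @export
generate_followup <- function(dataset, interval = NULL, g = NULL,
                              noise_sd = NULL) {
  gt <- dataset$ground_truth
  cfg <- gt$config
  if (is.null(interval)) interval <- cfg$follow_up_interval
  if (is.null(g)) g <- cfg$followup_accel
  if (interval < 0) stop("interval must be >= 0")
  with_seed(cfg$seed + 1L, {
    coefs <- gt$region_coefs
    sex <- gt$sex01
    eff_interval <- interval * (1 + g * gt$delta)
    X1 <- dataset$features
    meta <- attr(X1, "feature_meta")
    X2 <- X1
    for (r in seq_len(ncol(X1))) {
      slope <- coefs$slope_age[r] + coefs$sex_age[r] * sex
      sd_r <- if (is.null(noise_sd)) coefs$noise_sd[r] else noise_sd
      X2[, r] <- X1[, r] + slope * eff_interval +
        if (sd_r > 0) stats::rnorm(nrow(X1), 0, sd_r) else 0
    }
    attr(X2, "feature_meta") <- meta
    attr(X2, "state") <- "raw"
    X2
  })
}

#' Write a generated dataset to plain-text files
#'
#' Cohort, features and biomarkers as CSV; ground truth as JSON; the config
#' as YAML; plus a FreeSurfer `aparcstats2table`-style TSV of the features.
#'
#' @param dataset output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "features.csv", "biomarkers.csv",
                            "ground_truth.json", "config.yaml",
                            "aparcstats.tsv"))
  utils::write.csv(dataset$cohort, paths[1], row.names = FALSE)
  feat <- data.frame(subject_id = rownames(dataset$features),
                     dataset$features, check.names = FALSE)
  utils::write.csv(feat, paths[2], row.names = FALSE)
  utils::write.csv(dataset$biomarkers, paths[3], row.names = FALSE)
  gt <- dataset$ground_truth
  gt$config <- NULL
  gt$feature_meta <- NULL
  gt$region_coefs$site_eff <- as.data.frame(gt$region_coefs$site_eff)
  jsonlite::write_json(gt, paths[4], digits = NA, auto_unbox = TRUE)
  cfg <- unclass(dataset$ground_truth$config %||%
                   attr(dataset, "config"))
  if (!is.null(cfg)) {
    cfg$effects <- lapply(cfg$effects, as.list)
    yaml::write_yaml(cfg, paths[5])
  }
  tsv <- data.frame(`aparc.measure` = rownames(dataset$features),
                    dataset$features, check.names = FALSE)
  utils::write.table(tsv, paths[6], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
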