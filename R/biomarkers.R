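#' Load the amyloid/tau cut-off table
#'
#' Cut-offs ship as an editable versioned YAML file.  The defaults are the
#' published per-cohort values: CSF amyloid-beta 42 below 1098 pg/mL is
#' abnormal for the ALFA+ and EPAD assays and below 880 pg/mL for ADNI;
#' CSF p-tau181 above 24 pg/mL is abnormal in all CSF cohorts; amyloid-PET
#' above 17 Centiloids is abnormal for OASIS.  Values exactly at a cut-off
#' are classified normal (strict inequality).
#'
#' @param path optional path to a YAML file with the same structure as the
#'   shipped `inst/extdata/cutoffs.yaml`.
#' @return data.frame: `cohort`, `modality` ("csf"/"pet"), `abeta_cutoff`,
#'   `ptau_cutoff`.
#' @export
load_cutoffs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cutoffs.yaml", package = "neuroage")
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(y$cohorts), function(co) {
    e <- y$cohorts[[co]]
    if (!e$modality %in% c("csf", "pet"))
      stop("cohort ", co, ": modality must be 'csf' or 'pet'")
    if (e$abeta_cutoff <= 0 || e$ptau_cutoff <= 0)
      stop("cohort ", co, ": cut-offs must be positive")
    data.frame(cohort = co, modality = e$modality,
               abeta_cutoff = e$abeta_cutoff, ptau_cutoff = e$ptau_cutoff,
               stringsAsFactors = FALSE)
  }))
  attr(out, "version") <- y$version
  out
}

#' Amyloid-beta status from the cohort's modality
#'
#' Low CSF amyloid-beta 42 is abnormal; high PET Centiloid burden is
#' abnormal.  Strictly past the cut-off means abnormal: a CSF value exactly
#' at the cut-off (or a Centiloid value exactly at it) is `A-`.
#'
#' @param value biomarker value in the cohort's modality units (CSF pg/mL
#'   or Centiloids).  Negative Centiloids are legitimate; negative CSF
#'   concentrations are rejected.
#' @param cohort cohort label present in `cutoffs`.
#' @param cutoffs a [load_cutoffs()] table.
#' @return character vector of "A+" / "A-" (NA propagates).
#' @export
abeta_status <- function(value, cohort, cutoffs = load_cutoffs()) {
  cohort <- as.character(cohort)
  bad <- setdiff(unique(cohort), cutoffs$cohort)
  if (length(bad) > 0) stop("unknown cohort(s): ",
                            paste(bad, collapse = ", "))
  i <- match(cohort, cutoffs$cohort)
  modality <- cutoffs$modality[i]
  if (any(!is.na(value) & modality == "csf" & value < 0))
    stop("negative CSF concentration")
  ifelse(is.na(value), NA_character_,
         ifelse(modality == "csf",
                ifelse(value < cutoffs$abeta_cutoff[i], "A+", "A-"),
                ifelse(value > cutoffs$abeta_cutoff[i], "A+", "A-")))
}

#' AT stage from amyloid status and CSF p-tau
#'
#' T+ iff p-tau is strictly above the cut-off; the stage is the cross of
#' the two statuses.  Missing p-tau leaves the stage `NA`.
#'
#' @param abeta "A+"/"A-" per subject (see [abeta_status()]).
#' @param ptau_value CSF p-tau181, pg/mL.
#' @param cohort cohort label per subject.
#' @param cutoffs a [load_cutoffs()] table.
#' @return character vector in `{"A-T-", "A+T-", "A+T+", "A-T+"}`.
#' @export
at_stage <- function(abeta, ptau_value, cohort, cutoffs = load_cutoffs()) {
  i <- match(as.character(cohort), cutoffs$cohort)
  tpos <- ifelse(is.na(ptau_value), NA,
                 ptau_value > cutoffs$ptau_cutoff[i])
  ifelse(is.na(abeta) | is.na(tpos), NA_character_,
         paste0(abeta, ifelse(tpos, "T+", "T-")))
}

#' Exclude non-AD pathologic change (A-T+) subjects
#'
#' Subjects staged A-T+ fall outside the Alzheimer's continuum and are
#' removed before the association analyses.
#'
#' @param table data.frame with columns `at_stage` and (optionally)
#'   `cohort`.
#' @return the filtered table; attribute `exclusion_report` counts removed
#'   rows per cohort.
#' @export
exclude_non_ad_change <- function(table) {
  stopifnot("at_stage" %in% names(table))
  drop <- !is.na(table$at_stage) & table$at_stage == "A-T+"
  report <- if ("cohort" %in% names(table))
    table(cohort = table$cohort[drop]) else
    c(total = sum(drop))
  out <- table[!drop, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}

#' Aging-signature ROI weight template
#'
#' The aging-vulnerable meta-ROI is defined over the calcarine, caudal
#' fusiform, caudal insula, cuneus, inferior frontal gyrus, medial superior
#' frontal and precentral cortices.  Several of those labels have no exact
#' Desikan-Killiany counterpart; this template documents the chosen label
#' correspondence (an interpretation, overridable by the user) with
#' synthetic surface-area weights of realistic relative magnitude (mm^2,
#' per hemisphere-summed region).
#'
#' @return named numeric vector of weights over Desikan-Killiany labels.
#' @export
aging_signature_weights <- function() {
  c(pericalcarine = 2200,      # calcarine cortex
    fusiform = 2700,           # caudal fusiform
    insula = 3600,             # caudal insula
    cuneus = 1400,
    parsopercularis = 1600,    # inferior frontal gyrus (opercular part)
    parstriangularis = 1300,   # inferior frontal gyrus (triangular part)
    superiorfrontal = 6900,    # medial superior frontal
    precentral = 5000)
}

#' Surface-area weighted aging-signature composite
#'
#' `sum(w_r * t_r) / sum(w_r)` over the signature ROIs' mean cortical
#' thicknesses; the composite is in mm and always lies within the range of
#' its inputs.
#'
#' @param thickness named numeric vector or subjects x ROIs matrix of mean
#'   cortical thickness (mm), with names/colnames covering the weight
#'   names.
#' @param weights named non-negative weights, not all zero (default
#'   [aging_signature_weights()]); per-subject measured areas can be
#'   supplied as a matrix of the same shape as `thickness`.
#' @return numeric composite, one value per subject.
#' @export
aging_signature <- function(thickness, weights = aging_signature_weights()) {
  if (is.matrix(weights)) {
    stopifnot(identical(dim(weights), dim(thickness)),
              all(weights >= 0), all(rowSums(weights) > 0))
    return(rowSums(thickness * weights) / rowSums(weights))
  }
  stopifnot(all(weights >= 0), sum(weights) > 0)
  nms <- names(weights)
  if (is.matrix(thickness)) {
    if (!all(nms %in% colnames(thickness)))
      stop("missing signature ROI(s): ",
           paste(setdiff(nms, colnames(thickness)), collapse = ", "))
    as.numeric(thickness[, nms, drop = FALSE] %*% weights / sum(weights))
  } else {
    if (!all(nms %in% names(thickness)))
      stop("missing signature ROI(s): ",
           paste(setdiff(nms, names(thickness)), collapse = ", "))
    sum(thickness[nms] * weights) / sum(weights)
  }
}

#' Aging-signature composite from a full ROI feature matrix
#'
#' Extracts the signature ROIs' cortical thickness from a feature matrix
#' with `lh_<label>_thickness` / `rh_<label>_thickness` columns (hemisphere
#' means taken first) and computes the weighted composite.
#'
#' @param features subjects x features matrix (raw thickness scale).
#' @param weights named weights over Desikan-Killiany labels.
#' @return numeric composite per subject.
#' @export
signature_from_features <- function(features,
                                    weights = aging_signature_weights()) {
  lab <- names(weights)
  th <- sapply(lab, function(l) {
    cols <- intersect(paste0(c("lh_", "rh_"), l, "_thickness"),
                      colnames(features))
    if (length(cols) == 0) stop("missing signature ROI: ", l)
    rowMeans(features[, cols, drop = FALSE])
  })
  if (is.null(dim(th))) th <- matrix(th, nrow = 1, dimnames =
                                       list(NULL, lab))
  aging_signature(th, weights)
}

#' Z-score a signature value against a reference distribution
#'
#' @param values numeric vector.
#' @param reference_mean,reference_sd reference (e.g. cognitively
#'   unimpaired subjects') mean and SD; `reference_sd` must be > 0.
#' @return `(values - reference_mean) / reference_sd`.
#' @export
signature_zscore <- function(values, reference_mean, reference_sd) {
  if (reference_sd <= 0) stop("reference SD must be > 0")
  (values - reference_mean) / reference_sd
}

#' Longitudinal aging-signature change per year
#'
#' @param v1,v2 composite at visit 1 and visit 2 (mm).
#' @param interval years between visits (> 0).
#' @return `(v2 - v1) / interval`, mm per year.
#' @export
signature_change <- function(v1, v2, interval) {
  if (any(interval <= 0)) stop("interval must be > 0")
  (v2 - v1) / interval
}

#' Natural-log transform and z-score NfL within cohort
#'
#' Neurofilament light is right-skewed and assay scales differ across
#' cohorts/platforms; values are natural-log transformed then z-scored
#' feature-wise within cohort (all subjects of the cohort as reference) so
#' that cohorts can be pooled.
#'
#' @param values positive NfL concentrations (pg/mL).
#' @param cohort cohort label per value.
#' @return transformed numeric vector.
#' @export
transform_nfl <- function(values, cohort) {
  if (any(!is.na(values) & values <= 0)) stop("non-positive NfL value")
  lg <- log(values)
  out <- rep(NA_real_, length(lg))
  for (co in unique(as.character(cohort))) {
    idx <- which(cohort == co & !is.na(lg))
    out[idx] <- (lg[idx] - mean(lg[idx])) / stats::sd(lg[idx])
  }
  out
}

#' Prepare white-matter-hyperintensity volumes
#'
#' Natural-log transform, then residualize on total intracranial volume
#' with an intercept (ordinary least squares).
#'
#' @param wmh positive WMH volumes.
#' @param tiv total intracranial volume per subject.
#' @return residualized log-WMH values.
#' @export
prepare_wmh <- function(wmh, tiv) {
  if (any(!is.na(wmh) & wmh <= 0)) stop("non-positive WMH volume")
  ok <- !is.na(wmh) & !is.na(tiv)
  out <- rep(NA_real_, length(wmh))
  out[ok] <- stats::resid(stats::lm(log(wmh[ok]) ~ tiv[ok]))
  out
}

#' Stage a full biomarker panel
#'
#' Applies [abeta_status()] and [at_stage()] subject-wise, choosing CSF or
#' Centiloid input per the cohort's modality.
#'
#' @param biomarkers data.frame with `csf_ab42`, `csf_ptau`, `centiloid`
#'   columns (any may be missing/NA).
#' @param cohort cohort label per row.
#' @param cutoffs a [load_cutoffs()] table.
#' @return the input data.frame plus `abeta_status` and `at_stage` columns.
#' @export
stage_biomarkers <- function(biomarkers, cohort, cutoffs = load_cutoffs()) {
  i <- match(as.character(cohort), cutoffs$cohort)
  if (anyNA(i)) stop("unknown cohort(s): ",
                     paste(unique(cohort[is.na(i)]), collapse = ", "))
  avalue <- ifelse(cutoffs$modality[i] == "csf",
                   biomarkers$csf_ab42 %||% NA_real_,
                   biomarkers$centiloid %||% NA_real_)
  biomarkers$abeta_status <- abeta_status(avalue, cohort, cutoffs)
  biomarkers$at_stage <- at_stage(biomarkers$abeta_status,
                                  biomarkers$csf_ptau %||% NA_real_,
                                  cohort, cutoffs)
  biomarkers
}
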