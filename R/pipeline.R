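#' End-to-end brain-age pipeline on a generated or supplied dataset
#'
#' Convenience orchestration used by the examples and the acceptance
#' checks: harmonize features, fit sex-stratified models on the training
#' cohort, predict on the remaining cohorts, bias-correct per cohort,
#' stage biomarkers, and assemble the subject-level analysis table.
#'
#' @param dataset a [generate_cohort()]-style list (`cohort`, `features`,
#'   `biomarkers`).
#' @param train_cohort name of the cohort used for model training.
#' @param hyperparams_by_sex per-arm hyperparameters (default: a reduced
#'   fast profile, 300 trees at eta 0.08; pass
#'   `list(female = default_hyperparameters("female"), ...)` for the full
#'   published settings).
#' @param cv `c(folds, repeats)` for training-arm CV metrics; `c(0, 0)`
#'   (default) skips CV.
#' @param cutoffs a [load_cutoffs()] table; cohorts absent from it are
#'   staged with the first CSF entry's cut-offs.
#' @param followup optional visit-2 feature matrix (e.g. from
#'   [generate_followup()]); adds the aging-signature composite at both
#'   visits and its annualised change to the analysis table.
#' @param followup_interval years between visits (default: the dataset
#'   config's interval, else 3).
#' @param seed integer seed.
#' @return list: `model`, `analysis` (test-cohort data.frame with delta,
#'   staged biomarkers and transformed covariates), `train_metrics`.
#' @export
brainage_pipeline <- function(dataset, train_cohort,
                              hyperparams_by_sex = fast_hyperparameters(),
                              cv = c(0L, 0L), cutoffs = load_cutoffs(),
                              followup = NULL, followup_interval = NULL,
                              seed = 1L) {
  cohort <- dataset$cohort
  stopifnot(train_cohort %in% cohort$cohort)
  harm <- harmonize_features(dataset$features, cohort)

  tr <- cohort$cohort == train_cohort
  model <- fit_sex_stratified(harm[tr, , drop = FALSE], cohort$age[tr],
                              cohort$sex[tr], hyperparams_by_sex, cv = cv,
                              seed = seed)
  te <- !tr
  if (!any(te)) stop("no evaluation cohorts besides the training cohort")
  pred <- predict_brain_age(model, harm[te, , drop = FALSE],
                            cohort$sex[te])
  deltas <- brain_age_delta(pred, cohort$age[te], cohort$cohort[te])

  analysis <- cbind(cohort[te, , drop = FALSE],
                    deltas[, c("predicted", "corrected", "delta")])
  biom <- dataset$biomarkers[te, , drop = FALSE]
  staged_cohort <- analysis$cohort
  if (!all(unique(staged_cohort) %in% cutoffs$cohort)) {
    # synthetic cohorts: stage everything with the first CSF cut-offs
    csf <- cutoffs[cutoffs$modality == "csf", ][1, ]
    cutoffs <- do.call(rbind, lapply(unique(staged_cohort), function(co) {
      r <- csf; r$cohort <- co; r
    }))
  }
  biom <- stage_biomarkers(biom, staged_cohort, cutoffs)
  analysis <- cbind(analysis, biom[, setdiff(names(biom), "subject_id"),
                                   drop = FALSE])
  if (!is.null(analysis$csf_nfl))
    analysis$csf_nfl_z <- transform_nfl(analysis$csf_nfl, analysis$cohort)
  if (!is.null(analysis$plasma_nfl))
    analysis$plasma_nfl_z <- transform_nfl(analysis$plasma_nfl,
                                           analysis$cohort)
  if (!is.null(analysis$wmh))
    analysis$wmh_prepared <- prepare_wmh(analysis$wmh, analysis$tiv)
  if (!is.null(analysis$apoe))
    analysis$apoe_cat <- apoe_category(analysis$apoe)
  if (!is.null(followup)) {
    if (is.null(followup_interval))
      followup_interval <- tryCatch(
        dataset$ground_truth$config$follow_up_interval, error =
          function(e) 3)
    sig1 <- signature_from_features(dataset$features[te, , drop = FALSE])
    sig2 <- signature_from_features(followup[te, , drop = FALSE])
    cu <- analysis$diagnosis == "CU"
    analysis$signature_v1 <- signature_zscore(sig1, mean(sig1[cu]),
                                              stats::sd(sig1[cu]))
    analysis$signature_change <- signature_change(sig1, sig2,
                                                  followup_interval)
  }
  train_metrics <- model$cv_metrics
  list(model = model, analysis = analysis, train_metrics = train_metrics)
}

#' Reduced hyperparameter profile for fast fitting
#'
#' Same depth and regularisation style as the published optima but fewer,
#' faster-learning trees; used for simulations, tests and examples where
#' wall-clock matters more than the last fraction of a year of MAE.
#'
#' @return list with `female` and `male` hyperparameter lists.
#' @export
fast_hyperparameters <- function() {
  hp <- list(max_depth = 4L, nrounds = 300L, eta = 0.08, reg_alpha = 4,
             reg_lambda = 1, subsample = 0.4, gamma = 1,
             colsample_bytree = 0.9)
  list(female = hp, male = hp)
}
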