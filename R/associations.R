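.zscore <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) stop("cannot standardize a constant variable")
  (v - mean(v)) / s
}

#' Covariate-adjusted association of brain-age delta with one predictor
#'
#' Ordinary least squares of standardized delta on the predictor plus
#' covariates (default chronological age and sex; age only within
#' sex-stratified data).  Continuous predictors are z-scored before fitting
#' so the reported beta is standardized; categorical predictors are
#' dummy-coded against their reference level (beta then in outcome-SD units
#' per level).  Rows with missing values in any model variable are dropped
#' (complete-case; the per-test N is reported).  For continuous predictors
#' the effect size is Cohen's f^2 from the R-squared increment over the
#' covariate-only model.
#'
#' @param data data.frame containing `delta`, the predictor and covariates.
#' @param predictor column name of the predictor.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "sex")`).
#' @param reference reference level for a categorical predictor.
#' @return data.frame of class `association_result`, one row per predictor
#'   term: `predictor`, `level`, `beta`, `se`, `p`, `ci_low`, `ci_high`,
#'   `n`, `effect_size`, `effect_type`.
#' @export
fit_association <- function(data, predictor, covariates = c("age", "sex"),
                            reference = NULL) {
  stopifnot("delta" %in% names(data), predictor %in% names(data),
            all(covariates %in% names(data)), !predictor %in% covariates)
  vars <- c("delta", predictor, covariates)
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  if (nrow(d) <= length(vars) + 1) stop("empty or too-small stratum")

  x <- d[[predictor]]
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  d$delta <- .zscore(d$delta)
  if (categorical) {
    x <- as.character(x)
    lev <- unique(x)
    if (!is.null(reference)) {
      if (!reference %in% lev) stop("reference level absent")
      lev <- c(reference, sort(setdiff(lev, reference)))
    } else lev <- sort(lev)
    small <- names(which(table(x) < 2))
    if (length(small) > 0) stop("level(s) with < 2 subjects: ",
                                paste(small, collapse = ", "))
    d[[predictor]] <- factor(x, levels = lev)
  } else {
    d[[predictor]] <- .zscore(x)
  }
  for (cv in covariates)
    if (is.numeric(d[[cv]])) d[[cv]] <- .zscore(d[[cv]])

  fml <- stats::reformulate(c(predictor, covariates), response = "delta")
  fit <- stats::lm(fml, data = d)
  kappa_ <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (!is.finite(kappa_) || kappa_ > 1e10) stop("collinear design")
  sm <- summary(fit)
  ci <- stats::confint(fit)

  terms_keep <- grep(paste0("^", predictor), rownames(sm$coefficients),
                     value = TRUE)
  rows <- lapply(terms_keep, function(tm) {
    est <- sm$coefficients[tm, ]
    lvl <- if (categorical) sub(paste0("^", predictor), "", tm) else NA
    es <- if (categorical) {
      unname(est["Estimate"] / sm$sigma)  # Cohen's d on adjusted contrast
    } else if (sm$r.squared >= 1 - 1e-12) {
      Inf  # perfect fit: f^2 diverges
    } else {
      red <- stats::lm(stats::reformulate(covariates, response = "delta"),
                       data = d)
      cohens_f2(r2_full = sm$r.squared, r2_reduced =
                  summary(red)$r.squared)
    }
    data.frame(predictor = predictor, level = lvl,
               beta = unname(est["Estimate"]),
               se = unname(est["Std. Error"]),
               p = unname(est["Pr(>|t|)"]),
               ci_low = ci[tm, 1], ci_high = ci[tm, 2],
               n = nrow(d), effect_size = es,
               effect_type = if (categorical) "cohens_d" else "cohens_f2",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' ANCOVA-style contrasts of a categorical predictor
#'
#' One-way analysis of covariance adjusting for the covariates: each level
#' is contrasted against the reference; Cohen's d per contrast is the
#' adjusted difference divided by the model's residual SD.
#'
#' @inheritParams fit_association
#' @param reference reference level (required; e.g. "A-" for amyloid
#'   status, "A-T-" for AT stages, "e33" for APOE).
#' @return an `association_result` with one row per non-reference level.
#' @export
ancova_categorical <- function(data, predictor, reference,
                               covariates = c("age", "sex")) {
  x <- data[[predictor]]
  if (!(is.character(x) || is.factor(x)))
    stop("predictor must be categorical")
  fit_association(data, predictor, covariates, reference = reference)
}

#' Cohen's f-squared from nested model R-squared values
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`.
#'
#' @param r2_full,r2_reduced coefficients of determination of the full and
#'   reduced models, with `0 <= r2_reduced <= r2_full < 1`.
#' @return numeric effect size.
#' @export
cohens_f2 <- function(r2_full, r2_reduced) {
  if (r2_full >= 1) stop("R2 of the full model must be < 1")
  stopifnot(r2_reduced >= -1e-12, r2_reduced <= r2_full + 1e-12)
  (r2_full - r2_reduced) / (1 - r2_full)
}

#' Interaction of a predictor with a moderator on brain-age delta
#'
#' Fits `delta ~ predictor * moderator + covariates` with continuous
#' variables centered before products; returns the product-term row.
#'
#' @param data data.frame with `delta`, predictor, moderator, covariates.
#' @param predictor column name of the (continuous or binary) predictor.
#' @param moderator `"sex"` or `"age"` (or any column name).
#' @param covariates additional covariates (default: age and sex minus the
#'   moderator).
#' @return an `association_result` row for the interaction term.
#' @export
interaction_test <- function(data, predictor, moderator,
                             covariates = setdiff(c("age", "sex"),
                                                  moderator)) {
  vars <- unique(c("delta", predictor, moderator, covariates))
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars, drop = FALSE]
  if (length(unique(d[[moderator]])) < 2)
    stop("moderator constant within stratum")
  d$delta <- .zscore(d$delta)
  for (v in c(predictor, moderator, covariates))
    if (is.numeric(d[[v]])) d[[v]] <- scale(d[[v]], scale = FALSE)[, 1]
  if (is.numeric(d[[predictor]])) d[[predictor]] <-
      d[[predictor]] / stats::sd(d[[predictor]])
  fml <- stats::as.formula(paste(
    "delta ~", predictor, "*", moderator,
    if (length(covariates) > 0)
      paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  tm <- grep(":", rownames(sm$coefficients), value = TRUE)
  ci <- stats::confint(fit)
  out <- data.frame(predictor = paste0(predictor, ":", moderator),
                    level = NA, beta = sm$coefficients[tm, "Estimate"],
                    se = sm$coefficients[tm, "Std. Error"],
                    p = sm$coefficients[tm, "Pr(>|t|)"],
                    ci_low = ci[tm, 1], ci_high = ci[tm, 2], n = nrow(d),
                    effect_size = NA_real_, effect_type = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate q-values
#'
#' Step-up q-values over one family of tests; the family size is recorded
#' so users can reconstruct the multiplicity context.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values (same order as `p`), attribute `family_size`.
#' @export
fdr_correct <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values outside [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  attr(q, "family_size") <- sum(!is.na(p))
  q
}

#' Select extreme brain-age-delta subjects per cohort
#'
#' Keeps subjects whose delta is at or below the lower percentile or at or
#' above the upper percentile of their cohort's distribution (linear
#' interpolation percentiles, `stats::quantile` type 7).
#'
#' @param delta numeric deltas.
#' @param cohort cohort label per subject.
#' @param lower,upper percentile bounds (default 10 and 90).
#' @return logical vector selecting the extreme subjects; degenerate
#'   cohorts (empty tails from ties) trigger a warning.
#' @export
select_extreme_deltas <- function(delta, cohort = rep("all", length(delta)),
                                  lower = 10, upper = 90) {
  stopifnot(lower < upper)
  sel <- rep(FALSE, length(delta))
  for (co in unique(as.character(cohort))) {
    idx <- which(cohort == co & !is.na(delta))
    if (length(idx) < 10) stop("cohort ", co, " has fewer than 10 subjects")
    qs <- stats::quantile(delta[idx], c(lower, upper) / 100, type = 7)
    hit <- delta[idx] <= qs[1] | delta[idx] >= qs[2]
    if (all(hit) || !any(delta[idx] <= qs[1]) ||
        !any(delta[idx] >= qs[2]))
      warning("cohort ", co, ": degenerate delta tails (ties)")
    sel[idx[hit]] <- TRUE
  }
  sel
}

#' Run the full association battery
#'
#' Executes the configured tests across strata (pooled and per diagnosis,
#' each also sex-stratified), applies Benjamini-Hochberg FDR across the
#' entire battery as one family, and returns a tidy result table.  Spec
#' failures (e.g. an empty stratum) are recorded and skipped, not fatal.
#'
#' @param data subject-level data.frame containing `delta`, `age`, `sex`,
#'   `diagnosis`, plus the variables named in `specs`.
#' @param specs list of test specifications, each a list with `predictor`,
#'   optional `reference` (categorical), optional `interaction` moderator.
#'   Default: amyloid status, AT stage, APOE category, WMH, CSF/plasma NfL
#'   and signature change, mirroring the published battery.
#' @param strata named list of row filters; default: CU and MCI, overall
#'   and by sex.
#' @return tidy data.frame: stratum, predictor, level, beta, se, p, CI, n,
#'   effect size, `q` (BH-FDR across all rows); attribute `family_size`
#'   and `skipped` (character log of failed specs).
#' @export
run_battery <- function(data, specs = default_battery_specs(),
                        strata = default_strata(data)) {
  rows <- list(); skipped <- character()
  for (st in names(strata)) {
    d <- data[strata[[st]], , drop = FALSE]
    sex_stratified <- length(unique(d$sex)) < 2
    covs <- if (sex_stratified) "age" else c("age", "sex")
    for (sp in specs) {
      if (!sp$predictor %in% names(data)) next
      label <- paste0(st, ": ", sp$predictor,
                      if (!is.null(sp$interaction))
                        paste0(" x ", sp$interaction) else "")
      res <- tryCatch({
        if (!is.null(sp$interaction)) {
          if (sp$interaction == "sex" && sex_stratified)
            stop("sex interaction within a sex stratum")
          interaction_test(d, sp$predictor, sp$interaction,
                           covariates = setdiff(covs, sp$interaction))
        } else if (!is.null(sp$reference)) {
          ancova_categorical(d, sp$predictor, sp$reference, covs)
        } else {
          fit_association(d, sp$predictor, covs)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, paste0(label, " -- ", conditionMessage(res)))
      } else {
        res$stratum <- st
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- as.numeric(fdr_correct(out$p))
  out <- out[, c("stratum", setdiff(names(out), "stratum"))]
  attr(out, "family_size") <- nrow(out)
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  out
}

#' Default battery test specifications
#' @return list of spec lists (see [run_battery()]).
#' @export
default_battery_specs <- function() {
  list(
    list(predictor = "abeta_status", reference = "A-"),
    list(predictor = "at_stage", reference = "A-T-"),
    list(predictor = "apoe_cat", reference = "e33"),
    list(predictor = "wmh_prepared"),
    list(predictor = "csf_nfl_z"),
    list(predictor = "plasma_nfl_z"),
    list(predictor = "signature_change"),
    list(predictor = "wmh_prepared", interaction = "sex"),
    list(predictor = "csf_nfl_z", interaction = "sex"),
    list(predictor = "plasma_nfl_z", interaction = "sex"),
    list(predictor = "csf_nfl_z", interaction = "age"),
    list(predictor = "plasma_nfl_z", interaction = "age"))
}

#' Default strata: diagnosis crossed with all/female/male
#' @param data data.frame with `diagnosis` and `sex` columns.
#' @return named list of logical row filters.
#' @export
default_strata <- function(data) {
  out <- list()
  for (dg in intersect(c("CU", "MCI"), unique(data$diagnosis))) {
    out[[dg]] <- data$diagnosis == dg
    out[[paste0(dg, "_female")]] <- data$diagnosis == dg &
      data$sex == "female"
    out[[paste0(dg, "_male")]] <- data$diagnosis == dg &
      data$sex == "male"
  }
  out
}

#' Collapse APOE genotypes to the four analysis categories
#'
#' e33 (reference), e2 = \{e22, e23\}, e4 = \{e34, e44\}, e24 kept
#' separate.
#'
#' @param genotype character vector of genotypes ("e22", ..., "e44").
#' @return character vector in `{"e33", "e2", "e4", "e24"}`.
#' @export
apoe_category <- function(genotype) {
  g <- as.character(genotype)
  out <- rep(NA_character_, length(g))
  out[g == "e33"] <- "e33"
  out[g %in% c("e22", "e23")] <- "e2"
  out[g %in% c("e34", "e44")] <- "e4"
  out[g == "e24"] <- "e24"
  if (any(is.na(out) & !is.na(g)))
    stop("unknown genotype(s): ",
         paste(unique(g[is.na(out) & !is.na(g)]), collapse = ", "))
  out
}
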