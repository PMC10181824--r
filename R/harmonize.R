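#' Residualize ROI features for nuisance covariates
#'
#' Volumes are replaced by the residuals of an ordinary least-squares fit on
#' total intracranial volume (TIV) plus scanning-site indicators; cortical
#' thicknesses are residualized on site indicators only.  Fitting is done
#' within cohort.  Sites are one-hot coded against the most frequent site as
#' reference; a site observed for a single subject is pooled into the
#' reference level (with a warning) so the design stays full rank.
#'
#' @param features subjects x features numeric matrix carrying a
#'   `feature_meta` attribute (see [region_metadata()]); rows named by
#'   subject id.
#' @param covariates data.frame with columns `subject_id`, `cohort`, `site`,
#'   `tiv`, rows matching `features`.
#' @return residualized feature matrix with a `harmonization` attribute (the
#'   fitted [harmonization_model()]) and `state = "residualized"`.
#' @export
residualize <- function(features, covariates) {
  model <- harmonization_model(features, covariates)
  apply_residualization(model, features, covariates)
}

#' Fit a residualization model
#'
#' @inheritParams residualize
#' @return object of class `harmonization_model`: per cohort, the covariate
#'   design recipe and per-feature OLS coefficients.
#' @export
harmonization_model <- function(features, covariates) {
  meta <- attr(features, "feature_meta")
  if (is.null(meta)) stop("features must carry a 'feature_meta' attribute")
  stopifnot(nrow(features) == nrow(covariates),
            all(c("cohort", "site", "tiv") %in% names(covariates)))
  if (anyNA(covariates$tiv)) stop("missing TIV for volume residualization")
  is_vol <- meta$measure == "volume"
  fits <- list()
  for (co in unique(covariates$cohort)) {
    idx <- which(covariates$cohort == co)
    site <- as.character(covariates$site[idx])
    tab <- sort(table(site), decreasing = TRUE)
    ref <- names(tab)[1]
    singletons <- names(tab)[tab < 2]
    if (length(singletons) > 0 && any(singletons != ref)) {
      warning("cohort ", co, ": single-subject site(s) ",
              paste(setdiff(singletons, ref), collapse = ", "),
              " pooled into reference level ", ref)
      site[site %in% setdiff(singletons, ref)] <- ref
    }
    site <- factor(site, levels = c(ref, setdiff(sort(unique(site)), ref)))
    X_site <- if (nlevels(site) > 1)
      stats::model.matrix(~site)[, -1, drop = FALSE] else
      matrix(0, length(idx), 0)
    des_th <- cbind(`(Intercept)` = 1, X_site)
    des_vol <- cbind(`(Intercept)` = 1, tiv = covariates$tiv[idx], X_site)
    y <- features[idx, , drop = FALSE]
    beta_th <- if (any(!is_vol))
      qr.solve(qr(des_th), y[, !is_vol, drop = FALSE]) else
      matrix(0, ncol(des_th), 0)
    beta_vol <- if (any(is_vol))
      qr.solve(qr(des_vol), y[, is_vol, drop = FALSE]) else
      matrix(0, ncol(des_vol), 0)
    fits[[co]] <- list(ref_site = ref, site_levels = levels(site),
                       beta_thickness = beta_th, beta_volume = beta_vol)
  }
  structure(list(fits = fits, feature_meta = meta), class =
              "harmonization_model")
}

#' Apply a fitted residualization model to (possibly new) subjects
#'
#' @param model a [harmonization_model()].
#' @param features,covariates as in [residualize()].
#' @return residualized feature matrix.
#' @export
apply_residualization <- function(model, features, covariates) {
  meta <- model$feature_meta
  is_vol <- meta$measure == "volume"
  out <- features
  for (co in unique(covariates$cohort)) {
    fit <- model$fits[[co]]
    if (is.null(fit)) stop("no residualization model for cohort ", co)
    idx <- which(covariates$cohort == co)
    site <- as.character(covariates$site[idx])
    site[!site %in% fit$site_levels] <- fit$ref_site
    site <- factor(site, levels = fit$site_levels)
    X_site <- if (nlevels(site) > 1) {
      mm <- matrix(0, length(idx), nlevels(site) - 1,
                   dimnames = list(NULL, paste0("site",
                                                fit$site_levels[-1])))
      for (j in seq_len(ncol(mm)))
        mm[, j] <- as.numeric(site == fit$site_levels[j + 1])
      mm
    } else matrix(0, length(idx), 0)
    des_th <- cbind(`(Intercept)` = 1, X_site)
    des_vol <- cbind(`(Intercept)` = 1, tiv = covariates$tiv[idx], X_site)
    if (any(!is_vol))
      out[idx, !is_vol] <- features[idx, !is_vol, drop = FALSE] -
        des_th %*% fit$beta_thickness
    if (any(is_vol))
      out[idx, is_vol] <- features[idx, is_vol, drop = FALSE] -
        des_vol %*% fit$beta_volume
  }
  attr(out, "feature_meta") <- meta
  attr(out, "state") <- "residualized"
  attr(out, "harmonization") <- model
  out
}

#' Z-score features within cohort
#'
#' Feature-wise standardization within each cohort using the sample SD
#' (denominator n - 1).  Constant features are set to 0 and flagged.
#'
#' @param features subjects x features numeric matrix.
#' @param cohort_labels character/factor vector, one label per row.
#' @return standardized matrix; attributes `scaling` (per-cohort means/SDs)
#'   and `constant_features` (per-cohort list of flagged names);
#'   `state = "zscored"`.
#' @export
zscore_within_cohort <- function(features, cohort_labels) {
  stopifnot(nrow(features) == length(cohort_labels))
  out <- features
  scaling <- list()
  flagged <- list()
  for (co in unique(as.character(cohort_labels))) {
    idx <- which(cohort_labels == co)
    if (length(idx) < 2) stop("cohort ", co, " has fewer than 2 subjects")
    mu <- colMeans(features[idx, , drop = FALSE])
    sd_ <- apply(features[idx, , drop = FALSE], 2, stats::sd)
    const <- sd_ <= 0 | !is.finite(sd_)
    sd_safe <- ifelse(const, 1, sd_)
    out[idx, ] <- sweep(sweep(features[idx, , drop = FALSE], 2, mu), 2,
                        sd_safe, "/")
    out[idx, const] <- 0
    scaling[[co]] <- list(mean = mu, sd = sd_)
    flagged[[co]] <- colnames(features)[const]
  }
  attr(out, "feature_meta") <- attr(features, "feature_meta")
  attr(out, "scaling") <- scaling
  attr(out, "constant_features") <- flagged
  attr(out, "state") <- "zscored"
  out
}

#' Subset a feature matrix without losing its metadata
#'
#' Plain `[` subsetting on a matrix drops the `feature_meta`/`state`
#' attributes; this keeps them (and subsets `feature_meta` along columns).
#'
#' @param features feature matrix with a `feature_meta` attribute.
#' @param rows,cols index vectors (default: keep all).
#' @return the subset matrix with attributes carried over.
#' @export
subset_features <- function(features, rows = seq_len(nrow(features)),
                            cols = seq_len(ncol(features))) {
  out <- features[rows, cols, drop = FALSE]
  meta <- attr(features, "feature_meta")
  if (!is.null(meta))
    attr(out, "feature_meta") <- meta[match(colnames(out), meta$feature), ]
  attr(out, "state") <- attr(features, "state")
  out
}

#' Full preprocessing: residualize then z-score within cohort
#'
#' @inheritParams residualize
#' @return harmonized feature matrix ready for model fitting.
#' @export
harmonize_features <- function(features, covariates) {
  res <- residualize(features, covariates)
  zscore_within_cohort(res, covariates$cohort)
}
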