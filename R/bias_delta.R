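#' Fit the linear age-bias model
#'
#' Brain-age predictions regress toward the training mean: young subjects
#' are over-predicted and old subjects under-predicted.  The bias model is
#' the ordinary least-squares regression of predicted age Y on chronological
#' age: `Y = alpha * age + beta`.
#'
#' @param age,predicted paired numeric vectors (>= 3 subjects for SEs; 2
#'   points give the exact interpolating line with `NA` SEs).
#' @param sample_id optional identifier of the fitting sample, stored for
#'   provenance.
#' @return object of class `bias_model`: `alpha`, `beta`, their standard
#'   errors, `n`, `sample_id`.
#' @export
fit_age_bias <- function(age, predicted, sample_id = NULL) {
  stopifnot(length(age) == length(predicted), length(age) >= 2)
  if (stats::sd(age) == 0) stop("age is constant; bias model undefined")
  fit <- stats::lm(predicted ~ age)
  cf <- stats::coef(fit)
  # exact fits (e.g. predicted == age fixtures) make lm's summary warn
  se <- if (length(age) >= 3)
    suppressWarnings(sqrt(diag(stats::vcov(fit)))) else
    c(NA_real_, NA_real_)
  structure(list(alpha = unname(cf[2]), beta = unname(cf[1]),
                 se_alpha = unname(se[2]), se_beta = unname(se[1]),
                 n = length(age), sample_id = sample_id),
            class = "bias_model")
}

#' Age-bias-corrected prediction and brain-age delta
#'
#' Applies `corrected = predicted + (age - (alpha * age + beta))` and
#' `delta = corrected - age`.  Algebraically `delta` equals the residual of
#' the prediction from the bias line, so when the bias model is fit on the
#' very sample being corrected, delta is exactly orthogonal to age.
#'
#' @param predicted,age paired numeric vectors.
#' @param bias a [fit_age_bias()] model.
#' @return data.frame with `predicted`, `corrected`, `delta` (years).
#' @export
correct_and_delta <- function(predicted, age, bias) {
  stopifnot(inherits(bias, "bias_model"),
            length(predicted) == length(age))
  corrected <- predicted + (age - (bias$alpha * age + bias$beta))
  data.frame(predicted = predicted, corrected = corrected,
             delta = corrected - age)
}

#' Compute brain-age delta per cohort (or with a frozen bias model)
#'
#' Default behaviour fits the bias model within each evaluation cohort and
#' corrects that cohort with its own fit (this also removes cohort-level
#' offsets and makes delta exactly age-orthogonal per cohort).
#' Alternatively a single frozen `bias` model, e.g. from a training
#' reference sample, is applied to every cohort.
#'
#' @param predicted,age numeric vectors.
#' @param cohort cohort label per subject.
#' @param bias optional frozen [fit_age_bias()] model; if `NULL` (default)
#'   a model is fit per cohort.
#' @return data.frame with `cohort`, `predicted`, `corrected`, `delta`;
#'   attribute `bias_models` (per-cohort list).
#' @export
brain_age_delta <- function(predicted, age, cohort, bias = NULL) {
  stopifnot(length(predicted) == length(age),
            length(age) == length(cohort))
  out <- data.frame(cohort = as.character(cohort), predicted = predicted,
                    corrected = NA_real_, delta = NA_real_,
                    stringsAsFactors = FALSE)
  models <- list()
  for (co in unique(out$cohort)) {
    idx <- which(out$cohort == co)
    b <- if (is.null(bias))
      fit_age_bias(age[idx], predicted[idx], sample_id = co) else bias
    cd <- correct_and_delta(predicted[idx], age[idx], b)
    out$corrected[idx] <- cd$corrected
    out$delta[idx] <- cd$delta
    models[[co]] <- b
  }
  attr(out, "bias_models") <- models
  out
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("Age-bias model: Y = %.4f * age + %.3f  (n = %d%s)\n",
              x$alpha, x$beta, x$n,
              if (is.null(x$sample_id)) "" else
                paste0(", sample ", x$sample_id)))
  invisible(x)
}
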