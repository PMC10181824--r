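#' Published-style hyperparameter optima for the sex-stratified models
#'
#' Returns the default boosted-tree hyperparameters for each sex arm.  These
#' are the settings found by sequential model-based (Bayesian) optimization
#' under a 10-fold, 10-repeat cross-validation on a large training cohort:
#' both arms use depth-4 trees with learning rate 0.03; males use 800 trees,
#' alpha = 4, lambda = 1, subsample = 0.36, gamma = 3, colsample = 0.89;
#' females use 850 trees, alpha = 8.5, lambda = 14.5, subsample = 0.449,
#' gamma = 3.5, colsample = 0.72.
#'
#' @param sex "male" or "female".
#' @return named list of hyperparameters understood by [gbt_fit()].
#' @export
default_hyperparameters <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male")
    list(max_depth = 4L, nrounds = 800L, eta = 0.03, reg_alpha = 4,
         reg_lambda = 1, subsample = 0.36, gamma = 3,
         colsample_bytree = 0.89)
  else
    list(max_depth = 4L, nrounds = 850L, eta = 0.03, reg_alpha = 8.5,
         reg_lambda = 14.5, subsample = 0.449, gamma = 3.5,
         colsample_bytree = 0.72)
}

.validate_hyperparameters <- function(hp) {
  stopifnot(hp$max_depth >= 1, hp$nrounds >= 1,
            hp$subsample > 0, hp$subsample <= 1,
            hp$colsample_bytree > 0, hp$colsample_bytree <= 1)
  hp
}

# repeated k-fold assignments: list of integer vectors (test indices)
make_cv_folds <- function(n, folds, repeats, seed) {
  with_seed(seed, {
    out <- list()
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      grp <- cut(seq_len(n), breaks = folds, labels = FALSE)
      for (k in seq_len(folds))
        out[[length(out) + 1L]] <- sort(perm[grp == k])
    }
    out
  })
}

.fit_with_hp <- function(x, y, hp, seed) {
  gbt_fit(x, y, nrounds = hp$nrounds, max_depth = hp$max_depth,
          eta = hp$eta, subsample = hp$subsample,
          colsample_bytree = hp$colsample_bytree,
          reg_alpha = hp$reg_alpha, reg_lambda = hp$reg_lambda,
          gamma = hp$gamma, seed = seed)
}

# mean CV objective for one hyperparameter point
cv_objective <- function(x, y, hp, folds, repeats, seed,
                         objective = c("mae", "rmse")) {
  objective <- match.arg(objective)
  fold_idx <- make_cv_folds(nrow(x), folds, repeats, seed)
  errs <- vapply(seq_along(fold_idx), function(i) {
    test <- fold_idx[[i]]
    fit <- .fit_with_hp(x[-test, , drop = FALSE], y[-test], hp,
                        seed = seed + i)
    e <- predict(fit, x[test, , drop = FALSE]) - y[test]
    if (objective == "mae") mean(abs(e)) else sqrt(mean(e^2))
  }, 0)
  list(mean = mean(errs), sd = stats::sd(errs), per_fold = errs)
}

#' Tune boosted-tree hyperparameters by cross-validated search
#'
#' Sequential model-based search ("smbo", default): an initial random stage
#' is followed by stages that propose perturbations around the incumbent
#' best point (a simple trust-region style sequential strategy).  A "grid"
#' fallback evaluates every point of an explicit grid.  The objective is the
#' mean cross-validated MAE (or RMSE) in years.
#'
#' @param x,y training features (matrix) and ages for one sex arm.
#' @param search_space named list of length-2 numeric ranges (continuous) or
#'   explicit candidate vectors (for `"grid"`); parameters absent from the
#'   space are pinned at `base` values.
#' @param budget number of evaluated configurations (>= 1).
#' @param folds,repeats cross-validation scheme (default 10 x 10 is the
#'   reference scheme; use smaller values for exploratory work).
#' @param seed integer seed.
#' @param method "smbo" or "grid".
#' @param base hyperparameter list used for parameters not searched.
#' @param objective "mae" (default) or "rmse".
#' @return best hyperparameter list; attributes `trace` (data.frame of all
#'   evaluations) and `objective`.
#' @export
tune_hyperparameters <- function(x, y, search_space, budget = 20L,
                                 folds = 10L, repeats = 10L, seed = 1L,
                                 method = c("smbo", "grid"),
                                 base = default_hyperparameters("male"),
                                 objective = "mae") {
  method <- match.arg(method)
  if (budget < 1) stop("budget must be >= 1")
  if (length(search_space) == 0) stop("empty search space")
  int_params <- c("max_depth", "nrounds")

  make_point <- function(vals) {
    hp <- base
    for (nm in names(vals)) {
      v <- vals[[nm]]
      hp[[nm]] <- if (nm %in% int_params) as.integer(round(v)) else v
    }
    .validate_hyperparameters(hp)
  }

  candidates <- if (method == "grid") {
    grid <- expand.grid(search_space, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else NULL

  trace <- list()
  best <- NULL
  eval_point <- function(vals, stage) {
    hp <- make_point(vals)
    res <- cv_objective(x, y, hp, folds, repeats, seed,
                        objective = objective)
    row <- c(vals, list(.objective = res$mean, .sd = res$sd,
                        .stage = stage))
    trace[[length(trace) + 1L]] <<- row
    if (is.null(best) || res$mean < best$score)
      best <<- list(hp = hp, vals = vals, score = res$mean)
    invisible(res$mean)
  }

  with_seed(seed, {
    if (method == "grid") {
      for (i in seq_len(min(budget, length(candidates))))
        eval_point(candidates[[i]], "grid")
    } else {
      n_init <- max(1L, min(budget, ceiling(budget / 2)))
      draw_uniform <- function() {
        vals <- lapply(search_space, function(rg) {
          stats::runif(1, min(rg), max(rg))
        })
        vals
      }
      for (i in seq_len(n_init)) eval_point(draw_uniform(), "init")
      i <- n_init
      while (i < budget) {
        i <- i + 1
        vals <- lapply(names(search_space), function(nm) {
          rg <- search_space[[nm]]
          width <- (max(rg) - min(rg)) * 0.25
          v <- stats::rnorm(1, as.numeric(best$vals[[nm]]), width)
          min(max(v, min(rg)), max(rg))
        })
        names(vals) <- names(search_space)
        eval_point(vals, "refine")
      }
    }
  })

  out <- best$hp
  attr(out, "trace") <- do.call(rbind, lapply(trace, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "objective") <- objective
  out
}

#' Fit sex-stratified brain-age models
#'
#' Trains one boosted-tree regressor per sex on that sex's subjects only,
#' reports cross-validated performance per arm as mean (SD) over all
#' folds x repeats, then refits each arm on all of its data.
#'
#' @param features harmonized subjects x features matrix.
#' @param age numeric chronological ages (years).
#' @param sex character vector, "female"/"male" per subject.
#' @param hyperparams_by_sex list with elements `female` and `male` (each a
#'   hyperparameter list); default: [default_hyperparameters()] per arm.
#' @param cv `c(folds, repeats)`; use `c(0, 0)` to skip CV entirely.
#' @param seed integer seed (fold assignment and ensemble sampling).
#' @return object of class `sex_stratified_model`: fitted arms, locked
#'   feature schema, per-arm CV metrics (`cv_metrics`), and a per-fold log
#'   (`cv_log`).
#' @export
fit_sex_stratified <- function(features, age, sex,
                               hyperparams_by_sex = list(
                                 female = default_hyperparameters("female"),
                                 male = default_hyperparameters("male")),
                               cv = c(10L, 10L), seed = 1L) {
  stopifnot(nrow(features) == length(age), length(age) == length(sex))
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male")))
    stop("sex labels must be 'female' or 'male'")
  folds <- as.integer(cv[1]); repeats <- as.integer(cv[2])
  arms <- list(); cv_metrics <- list(); cv_log <- list()
  for (s in c("female", "male")) {
    idx <- which(sex == s)
    if (length(idx) == 0) stop("no subjects for sex arm ", s)
    if (folds > 0 && length(idx) < folds)
      stop("sex arm ", s, " has fewer subjects (", length(idx),
           ") than CV folds (", folds, ")")
    xs <- features[idx, , drop = FALSE]
    ys <- age[idx]
    hp <- .validate_hyperparameters(hyperparams_by_sex[[s]])
    if (folds > 0) {
      fold_idx <- make_cv_folds(length(idx), folds, repeats, seed)
      per_fold <- lapply(seq_along(fold_idx), function(i) {
        test <- fold_idx[[i]]
        fit <- .fit_with_hp(xs[-test, , drop = FALSE], ys[-test], hp,
                            seed = seed + i)
        evaluate_predictions(predict(fit, xs[test, , drop = FALSE]),
                             ys[test])
      })
      mat <- do.call(rbind, lapply(per_fold, function(m)
        unlist(m[c("R", "MAE", "R2", "RMSE")])))
      cv_metrics[[s]] <- list(
        mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
        n_fits = nrow(mat))
      cv_log[[s]] <- data.frame(
        fold = rep(seq_len(folds), repeats),
        repeat_ = rep(seq_len(repeats), each = folds), mat)
    }
    arms[[s]] <- .fit_with_hp(xs, ys, hp, seed = seed)
  }
  structure(list(arms = arms, feature_names = colnames(features),
                 cv_metrics = cv_metrics, cv_log = cv_log,
                 cv_scheme = c(folds = folds, repeats = repeats),
                 seed = seed),
            class = "sex_stratified_model")
}

#' Predict brain-age, routing each subject to their sex arm
#'
#' @param model a [fit_sex_stratified()] model.
#' @param features harmonized features with the training column schema.
#' @param sex character vector of "female"/"male" labels.
#' @return numeric vector of raw (uncorrected) predicted ages, years.
#' @export
predict_brain_age <- function(model, features, sex) {
  stopifnot(inherits(model, "sex_stratified_model"),
            nrow(features) == length(sex))
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("female", "male"))
  if (length(bad) > 0) stop("unknown sex label(s): ",
                            paste(bad, collapse = ", "))
  if (!identical(colnames(features), model$feature_names))
    stop("feature columns do not match the training schema")
  out <- rep(NA_real_, nrow(features))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    out[idx] <- predict(model$arms[[s]], features[idx, , drop = FALSE])
  }
  out
}

#' Prediction performance metrics
#'
#' MAE, RMSE, Pearson R (with p-value) and R-squared, where R-squared is the
#' squared Pearson correlation between prediction and age (not
#' 1 - RSS/TSS); on biased predictions the two differ, and the squared
#' correlation matches how such models are conventionally summarised next
#' to R.
#'
#' @param predicted,age paired numeric vectors (>= 3 subjects).
#' @return list with `R`, `p`, `MAE`, `R2`, `RMSE`.
#' @export
evaluate_predictions <- function(predicted, age) {
  stopifnot(length(predicted) == length(age), length(age) >= 3)
  if (stats::sd(age) == 0) stop("age has zero variance")
  err <- predicted - age
  ct <- if (stats::sd(predicted) > 0)
    stats::cor.test(predicted, age) else list(estimate = NA_real_,
                                              p.value = NA_real_)
  r <- unname(ct$estimate)
  list(R = r, p = ct$p.value, MAE = mean(abs(err)), R2 = r^2,
       RMSE = sqrt(mean(err^2)))
}

#' Compare two independent Pearson correlations (Fisher z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,n1,r2,n2 correlations and sample sizes (n > 3, |r| < 1).
#' @return list with `z` and `p`.
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 3, n2 > 3)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Williams test for two dependent correlations sharing a variable
#'
#' Compares `r_jk` and `r_jh` (both involving variable j) given `r_kh`, on
#' `n - 3` degrees of freedom; two-sided p-value.
#'
#' @param r_jk,r_jh,r_kh the three pairwise correlations.
#' @param n sample size (> 3).
#' @return list with `t`, `df`, `p`.
#' @export
williams_test <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n > 3)
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("correlations do not form a PSD matrix")
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  rbar <- (r_jk + r_jh) / 2
  tstat <- (r_jk - r_jh) * sqrt(
    ((n - 1) * (1 + r_kh)) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_kh)^3))
  list(t = tstat, df = n - 3,
       p = 2 * stats::pt(-abs(tstat), df = n - 3))
}

#' Variance-ratio F test between two fitted models
#'
#' Compares residual mean squares of two models fit on the same outcomes:
#' `F = (rss_a / df_a) / (rss_b / df_b)` with `df = n - p`; two-sided
#' p-value.
#'
#' @param rss_a,rss_b residual sums of squares.
#' @param p_a,p_b numbers of fitted parameters (including intercepts).
#' @param n common sample size.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
compare_models_ftest <- function(rss_a, p_a, rss_b, p_b, n) {
  stopifnot(n > max(p_a, p_b))
  if (rss_a <= 0 || rss_b <= 0) stop("zero residual variance")
  df1 <- n - p_a; df2 <- n - p_b
  Fstat <- (rss_a / df1) / (rss_b / df2)
  p <- 2 * min(stats::pf(Fstat, df1, df2),
               1 - stats::pf(Fstat, df1, df2))
  list(F = Fstat, df1 = df1, df2 = df2, p = min(p, 1))
}

#' @export
print.sex_stratified_model <- function(x, ...) {
  cat("Sex-stratified brain-age model\n")
  for (s in names(x$arms))
    cat(sprintf("  %s arm: %d trees, %d features\n", s,
                length(x$arms[[s]]$trees), length(x$feature_names)))
  for (s in names(x$cv_metrics)) {
    m <- x$cv_metrics[[s]]
    cat(sprintf("  %s CV (%d fits): MAE %.2f (%.2f), R %.3f (%.3f)\n", s,
                m$n_fits, m$mean["MAE"], m$sd["MAE"], m$mean["R"],
                m$sd["R"]))
  }
  invisible(x)
}
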