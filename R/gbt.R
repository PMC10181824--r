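#' @useDynLib neuroage, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run code with a temporary RNG state so fitting never disturbs the caller's
# random stream (and is reproducible from `seed` alone).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Gradient-boosted regression trees
#'
#' Fits an ensemble of depth-limited regression trees by gradient boosting
#' with squared-error loss.  Regularisation follows the standard boosted-tree
#' parameterisation: L1 (`reg_alpha`) and L2 (`reg_lambda`) penalties on leaf
#' weights, a minimum split gain (`gamma`), shrinkage (`eta`), and per-tree
#' row (`subsample`) and column (`colsample_bytree`) subsampling.
#'
#' @param x numeric matrix of predictors (rows = subjects). Column names are
#'   recorded and enforced at prediction time.
#' @param y numeric response vector (here: chronological age in years).
#' @param nrounds number of boosting rounds (trees).
#' @param max_depth maximum tree depth.
#' @param eta learning rate in (0, 1].
#' @param subsample,colsample_bytree row/column sampling fractions in (0, 1].
#' @param reg_alpha,reg_lambda,gamma regularisation parameters (>= 0).
#' @param min_child_weight minimum hessian (= row count for squared error)
#'   per child node.
#' @param seed integer seed controlling the subsampling streams.
#' @return An object of class `gbt`: list with `trees` (flat node matrices),
#'   `base_score`, `feature_names` and the fitting parameters.
#' @export
gbt_fit <- function(x, y, nrounds = 300L, max_depth = 4L, eta = 0.05,
                    subsample = 1, colsample_bytree = 1, reg_alpha = 0,
                    reg_lambda = 1, gamma = 0, min_child_weight = 1,
                    seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrounds >= 1, max_depth >= 1,
            eta > 0, eta <= 1, subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1,
            reg_alpha >= 0, reg_lambda >= 0, gamma >= 0)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n <- nrow(x); p <- ncol(x)
  n_sub <- max(2L, as.integer(round(subsample * n)))
  p_sub <- max(1L, as.integer(round(colsample_bytree * p)))

  samp <- with_seed(seed, {
    rows <- vapply(seq_len(nrounds),
                   function(i) sample.int(n, n_sub) - 1L,
                   integer(n_sub))
    cols <- lapply(seq_len(nrounds),
                   function(i) sort(sample.int(p, p_sub)) - 1L)
    list(rows = matrix(rows, nrow = n_sub), cols = cols)
  })

  fit <- .gbt_fit_cpp(x, y, as.integer(nrounds), as.integer(max_depth),
                      eta, reg_alpha, reg_lambda, gamma, min_child_weight,
                      samp$rows, samp$cols)
  structure(
    list(trees = fit$trees, base_score = fit$base_score,
         feature_names = colnames(x),
         params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                       subsample = subsample,
                       colsample_bytree = colsample_bytree,
                       reg_alpha = reg_alpha, reg_lambda = reg_lambda,
                       gamma = gamma, min_child_weight = min_child_weight,
                       seed = seed)),
    class = "gbt")
}

# Check (and if needed reorder is NOT allowed -- refuse) the feature schema.
gbt_check_schema <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(object$feature_names) &&
      (is.null(colnames(x)) || !identical(colnames(x), object$feature_names)))
    stop("feature columns do not match the training schema ",
         "(same names, same order required)")
  x
}

#' Predict from a gradient-boosted tree model
#'
#' @param object a fitted [gbt_fit()] model.
#' @param newdata numeric matrix with the training column schema.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbt <- function(object, newdata, ...) {
  x <- gbt_check_schema(object, newdata)
  as.numeric(.gbt_predict_cpp(object$trees, object$base_score, x))
}

#' Exact tree-Shapley attributions for a boosted-tree model
#'
#' Computes additive per-feature attributions using the path-dependent
#' polynomial-time recursion over the tree structure; the value function is
#' the conditional expectation implied by training-sample node covers.
#' Attributions satisfy local accuracy: for every row,
#' `expected_value + sum(attributions) == prediction`.
#'
#' @param object a fitted [gbt_fit()] model.
#' @param newdata numeric matrix with the training column schema.
#' @return numeric matrix (rows x features) of attributions with attribute
#'   `expected_value` (the model's training-mean prediction).
#' @export
gbt_shap <- function(object, newdata) {
  x <- gbt_check_schema(object, newdata)
  res <- .gbt_shap_cpp(object$trees, object$base_score, x)
  phi <- res$phi
  dimnames(phi) <- list(rownames(x), object$feature_names)
  attr(phi, "expected_value") <- res$expected_value
  phi
}

#' @export
print.gbt <- function(x, ...) {
  cat("Gradient-boosted tree regressor\n")
  cat(sprintf("  trees: %d, max depth: %d, eta: %g\n",
              length(x$trees), x$params$max_depth, x$params$eta))
  cat(sprintf("  features: %d, base score: %.3f\n",
              length(x$feature_names), x$base_score))
  invisible(x)
}
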