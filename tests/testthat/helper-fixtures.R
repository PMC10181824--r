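# Shared fixtures: small configurations and cached datasets, built in code.

# deterministic, noise-free world: features are exact functions of
# (age, sex, site, TIV); no latent acceleration
zero_noise_config <- function(n = 300L, n_regions = 12L, seed = 1L, ...) {
  sim_config(
    n_subjects = c(SIM = as.integer(n)),
    n_regions = n_regions,
    sigma_delta = 0,
    apoe_delta_shift = c(e22 = 0, e23 = 0, e33 = 0, e24 = 0, e34 = 0,
                         e44 = 0),
    apoe_pathology_shift = c(e22 = 0, e23 = 0, e33 = 0, e24 = 0, e34 = 0,
                             e44 = 0),
    noise_sd_thickness = 0, noise_sd_volume_frac = 0, shared_noise_sd = 0,
    sex_age_interaction_sd = 0,
    seed = seed, ...)
}

# small default-noise cohort reused across tests (built once per run)
.small_ds_cache <- new.env()
small_dataset <- function() {
  if (is.null(.small_ds_cache$ds))
    .small_ds_cache$ds <- generate_cohort(
      sim_config(n_subjects = c(TRAIN = 600L, TEST = 300L),
                 n_regions = 20L, seed = 42L))
  .small_ds_cache$ds
}

# tiny boosted-tree settings for fast retraining loops
tiny_hp <- function(nrounds = 60L, max_depth = 3L) {
  list(max_depth = max_depth, nrounds = nrounds, eta = 0.15,
       reg_alpha = 0, reg_lambda = 1, subsample = 1, gamma = 0,
       colsample_bytree = 1)
}

# brute-force Shapley values for a gbt model via exhaustive coalition
# enumeration with the cover-weighted conditional-expectation value function
brute_force_shap <- function(model, xrow) {
  p <- length(model$feature_names)
  expval <- function(tree, S) {
    rec <- function(nd) {
      f <- tree[nd, 1]
      if (f < 0) return(tree[nd, 5])
      if ((f + 1) %in% S) {
        if (xrow[f + 1] < tree[nd, 2]) rec(tree[nd, 3] + 1) else
          rec(tree[nd, 4] + 1)
      } else {
        l <- tree[nd, 3] + 1; r <- tree[nd, 4] + 1
        (tree[l, 6] * rec(l) + tree[r, 6] * rec(r)) / tree[nd, 6]
      }
    }
    rec(1)
  }
  vfun <- function(S) model$base_score +
    sum(vapply(model$trees, expval, 0, S = S))
  subsets <- lapply(0:(2^p - 1),
                    function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (S in subsets) {
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) /
        factorial(p)
      phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
    }
  }
  phi
}
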