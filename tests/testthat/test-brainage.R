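test_that("evaluate_predictions matches hand arithmetic", {
  m <- evaluate_predictions(c(62, 64, 73), c(60, 65, 70))
  expect_equal(m$MAE, 2.0)
  expect_equal(m$RMSE, 2.160, tolerance = 5e-4)
  expect_equal(m$R, 0.939, tolerance = 5e-4)

  exact <- evaluate_predictions(c(60, 65, 70), c(60, 65, 70))
  expect_equal(exact$MAE, 0)
  expect_equal(exact$RMSE, 0)
  expect_equal(exact$R, 1)

  shift <- evaluate_predictions(c(60, 65, 70) + 5, c(60, 65, 70))
  expect_equal(shift$MAE, 5)
  expect_equal(shift$R, 1)

  expect_error(evaluate_predictions(c(1, 2, 3), c(5, 5, 5)),
               "zero variance")
  expect_true(m$MAE <= m$RMSE)
})

test_that("defaults reproduce the published per-sex optima", {
  m <- default_hyperparameters("male")
  expect_equal(m[c("max_depth", "nrounds", "eta", "reg_alpha",
                   "reg_lambda", "subsample", "gamma",
                   "colsample_bytree")],
               list(max_depth = 4L, nrounds = 800L, eta = 0.03,
                    reg_alpha = 4, reg_lambda = 1, subsample = 0.36,
                    gamma = 3, colsample_bytree = 0.89))
  f <- default_hyperparameters("female")
  expect_equal(f[c("nrounds", "reg_alpha", "reg_lambda", "subsample",
                   "gamma", "colsample_bytree")],
               list(nrounds = 850L, reg_alpha = 8.5, reg_lambda = 14.5,
                    subsample = 0.449, gamma = 3.5,
                    colsample_bytree = 0.72))
})

test_that("tuner honours its budget and beats worse depths", {
  set.seed(4)
  n <- 250
  x <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 10 * (x[, 1] > 0.5) * (x[, 2] > 0.5) + x[, 3]  # needs depth >= 2

  # budget 1 on a collapsed space returns that point
  one <- tune_hyperparameters(x, y, list(max_depth = 3), budget = 1,
                              folds = 2, repeats = 1, seed = 1,
                              method = "grid", base = tiny_hp())
  expect_equal(one$max_depth, 3L)
  expect_equal(nrow(attr(one, "trace")), 1)

  # exhaustive oracle over {1, 3}: evaluate both depths directly
  best <- tune_hyperparameters(x, y, list(max_depth = c(1, 3)),
                               budget = 2, folds = 3, repeats = 1,
                               seed = 2, method = "grid",
                               base = tiny_hp())
  oracle <- sapply(c(1, 3), function(d) {
    hp <- tiny_hp(); hp$max_depth <- d
    neuroage:::cv_objective(x, y, hp, folds = 3, repeats = 1,
                            seed = 2)$mean
  })
  expect_equal(best$max_depth, c(1L, 3L)[which.min(oracle)])
  expect_equal(best$max_depth, 3L)  # interaction needs depth > 1

  expect_error(tune_hyperparameters(x, y, list(), budget = 2), "empty")
  expect_error(tune_hyperparameters(x, y, list(max_depth = c(1, 2)),
                                    budget = 0), "budget")

  # smbo mode runs within budget and returns a valid point
  sm <- tune_hyperparameters(x, y, list(eta = c(0.05, 0.3)), budget = 4,
                             folds = 2, repeats = 1, seed = 3,
                             base = tiny_hp())
  expect_equal(nrow(attr(sm, "trace")), 4)
  expect_true(sm$eta >= 0.05 && sm$eta <= 0.3)
})

test_that("sex arms are trained separately and routed correctly", {
  ds <- small_dataset()
  harm <- harmonize_features(ds$features, ds$cohort)
  idx <- ds$cohort$cohort == "TRAIN"
  x <- harm[idx, ]; age <- ds$cohort$age[idx]; sex <- ds$cohort$sex[idx]
  hp <- list(female = tiny_hp(), male = tiny_hp())
  m <- fit_sex_stratified(x, age, sex, hp, cv = c(3L, 2L), seed = 5)

  # bookkeeping: folds x repeats fits logged per arm
  expect_equal(nrow(m$cv_log$female), 6)
  expect_equal(m$cv_metrics$male$n_fits, 6)

  # routing: all-female table never touches the male arm
  f_idx <- which(sex == "female")[1:10]
  pf <- predict_brain_age(m, x[f_idx, ], rep("female", 10))
  expect_equal(pf, predict(m$arms$female, x[f_idx, ]))

  # arm separation: perturbing male training rows leaves female arm alone
  age2 <- age
  age2[sex == "male"] <- age2[sex == "male"] + 10
  m2 <- fit_sex_stratified(x, age2, sex, hp, cv = c(0L, 0L), seed = 5)
  expect_identical(predict(m2$arms$female, x[f_idx, ]), pf)

  # row-permutation equivariance
  te <- which(!idx)[1:40]
  perm <- sample(40)
  p1 <- predict_brain_age(m, harm[te, ], ds$cohort$sex[te])
  p2 <- predict_brain_age(m, harm[te, ][perm, ], ds$cohort$sex[te][perm])
  expect_equal(p2, p1[perm])

  expect_error(predict_brain_age(m, harm[te, ],
                                 rep("other", length(te))),
               "unknown sex label")
  expect_error(fit_sex_stratified(x[1:8, ], age[1:8], sex[1:8], hp,
                                  cv = c(10L, 1L), seed = 1),
               "fewer subjects")
})

test_that("noise-free training yields near-perfect age prediction", {
  cfg <- zero_noise_config(n = 1200, n_regions = 20, seed = 31)
  ds <- generate_cohort(cfg)
  harm <- harmonize_features(ds$features, ds$cohort)
  sex <- ds$cohort$sex
  hp <- tiny_hp(nrounds = 500L, max_depth = 4L)
  hp$eta <- 0.1
  m <- fit_sex_stratified(harm, ds$cohort$age, sex,
                          list(female = hp, male = hp), cv = c(3L, 1L),
                          seed = 2)
  for (s in c("female", "male"))
    expect_lt(m$cv_metrics[[s]]$mean["MAE"], 0.5)
})

test_that("held-out prediction quality sits in the default-world envelope", {
  cfg <- sim_config(n_subjects = c(TRAIN = 1200L, TEST = 400L),
                    seed = 60L)
  ds <- generate_cohort(cfg)
  pipe <- brainage_pipeline(ds, "TRAIN", seed = 60)
  r <- cor(pipe$analysis$predicted, pipe$analysis$age)
  expect_gte(r, 0.4)
  expect_lte(r, 0.9)
})

test_that("CV MAE improves with ensemble size on noise-free data", {
  cfg <- zero_noise_config(n = 400, n_regions = 12, seed = 61)
  ds <- generate_cohort(cfg)
  harm <- harmonize_features(ds$features, ds$cohort)
  res <- lapply(c(50L, 200L, 800L), function(nr) {
    hp <- tiny_hp(nrounds = nr, max_depth = 3L)
    hp$eta <- 0.05
    neuroage:::cv_objective(harm, ds$cohort$age, hp, folds = 3,
                            repeats = 1, seed = 62)
  })
  mae <- vapply(res, `[[`, 0, "mean")
  sds <- vapply(res, `[[`, 0, "sd")
  # monotone decrease, allowing fold-level SD slack
  expect_lt(mae[2], mae[1] + sds[1])
  expect_lt(mae[3], mae[2] + sds[2])
  expect_lt(mae[3], mae[1])
})

test_that("Fisher z comparison of independent correlations", {
  eq <- compare_correlations_independent(0.5, 100, 0.5, 250)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  r <- compare_correlations_independent(0.3, 103, 0.5, 103)
  expect_equal(r$z, -1.695, tolerance = 5e-4)
  expect_equal(r$p, 0.090, tolerance = 5e-3)

  sw <- compare_correlations_independent(0.5, 103, 0.3, 103)
  expect_equal(sw$z, -r$z)
  expect_equal(sw$p, r$p)
  expect_error(compare_correlations_independent(1, 10, 0.5, 10), "< 1")
})

test_that("Williams test agrees with an independent transcription", {
  sym <- williams_test(0.4, 0.4, 0.2, 50)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  # independent textbook-formula implementation
  oracle <- function(rjk, rjh, rkh, n) {
    detR <- (1 - rjk^2 - rjh^2 - rkh^2) + 2 * rjk * rjh * rkh
    rb <- mean(c(rjk, rjh))
    num <- (rjk - rjh) * sqrt((n - 1) * (1 + rkh))
    den <- sqrt(2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - rkh)^3)
    num / den
  }
  got <- williams_test(0.712, 0.5, 0.6, 380)
  expect_equal(got$t, oracle(0.712, 0.5, 0.6, 380), tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(got$t), 377))
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "PSD")
})

test_that("model-comparison F test", {
  same <- compare_models_ftest(10, 3, 10, 3, 30)
  expect_equal(same$F, 1)

  # brute-force from residuals on a toy n = 20 fixture
  set.seed(6)
  x <- rnorm(20); y <- 1 + 2 * x + rnorm(20)
  fa <- lm(y ~ 1); fb <- lm(y ~ x)
  got <- compare_models_ftest(sum(resid(fa)^2), 1, sum(resid(fb)^2), 2, 20)
  direct <- (sum(resid(fa)^2) / 19) / (sum(resid(fb)^2) / 18)
  expect_equal(got$F, direct)
  # scale invariance
  sc <- compare_models_ftest(sum(resid(fa)^2) * 7, 1,
                             sum(resid(fb)^2) * 7, 2, 20)
  expect_equal(sc$F, got$F)
  expect_error(compare_models_ftest(0, 1, 1, 2, 20), "zero residual")
})
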