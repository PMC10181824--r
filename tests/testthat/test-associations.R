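make_assoc_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  data.frame(delta = rnorm(n, 0, 3), age = runif(n, 45, 85),
             sex = sample(c("female", "male"), n, TRUE),
             biomarker = rnorm(n))
}

test_that("standardized beta is exact in the deterministic limit", {
  d <- make_assoc_data(200, 2)
  d$delta <- (d$biomarker - mean(d$biomarker)) / sd(d$biomarker)
  # lm warns about the (intentionally) perfect fit
  res <- suppressWarnings(fit_association(d, "biomarker"))
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-100)
  expect_equal(res$n, 200)
  expect_equal(res$effect_type, "cohens_f2")
  expect_equal(res$effect_size, Inf)
  # beta invariant to affine predictor rescaling
  d2 <- d; d2$biomarker <- d2$biomarker * 13 - 5
  expect_equal(suppressWarnings(fit_association(d2, "biomarker"))$beta,
               res$beta, tolerance = 1e-10)
})

test_that("type-I error of the association test is calibrated", {
  hits <- vapply(1:400, function(s) {
    d <- make_assoc_data(120, s + 1000)
    fit_association(d, "biomarker")$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)
})

test_that("ANCOVA contrasts recover planted group shifts as Cohen's d", {
  set.seed(3)
  n <- 800
  grp <- sample(c("A-", "A+"), n, TRUE)
  d <- data.frame(age = runif(n, 50, 80),
                  sex = sample(c("female", "male"), n, TRUE),
                  abeta = grp,
                  delta = 1.0 * (grp == "A+") + rnorm(n, 0, 2))
  res <- ancova_categorical(d, "abeta", reference = "A-")
  expect_equal(res$level, "A+")
  expect_equal(res$effect_size, 0.5, tolerance = 0.15)

  # identical distributions: null contrast
  d0 <- d; d0$delta <- rnorm(n, 0, 2)
  res0 <- ancova_categorical(d0, "abeta", reference = "A-")
  expect_lt(abs(res0$beta), 0.15)
  expect_error(ancova_categorical(d, "delta", reference = "x"),
               "categorical")
  expect_error(fit_association(d, "abeta", reference = "missing"),
               "reference level absent")
})

test_that("Cohen's f2 closed form and dual-route equivalence", {
  expect_equal(cohens_f2(0.5, 0.3), 0.4)
  expect_equal(cohens_f2(0.37, 0.37), 0)
  expect_error(cohens_f2(1, 0.5), "must be < 1")
  expect_error(cohens_f2(0.3, 0.5))

  # dual route: from fitted models on a fixture
  d <- make_assoc_data(150, 4)
  d$delta <- 0.4 * d$biomarker + rnorm(150)
  res <- fit_association(d, "biomarker")
  dz <- d
  dz$delta <- (d$delta - mean(d$delta)) / sd(d$delta)
  dz$biomarker <- (d$biomarker - mean(d$biomarker)) / sd(d$biomarker)
  dz$age <- (d$age - mean(d$age)) / sd(d$age)
  full <- summary(lm(delta ~ biomarker + age + sex, dz))$r.squared
  red <- summary(lm(delta ~ age + sex, dz))$r.squared
  expect_equal(res$effect_size, (full - red) / (1 - full),
               tolerance = 1e-10)
})

test_that("interaction tests are calibrated and detect moderation", {
  # coding antisymmetry: relabelling sexes flips the product-term sign
  d <- make_assoc_data(400, 5)
  d$delta <- d$delta + 0.5 * d$biomarker * (d$sex == "female")
  i1 <- interaction_test(d, "biomarker", "sex")
  d2 <- d
  d2$sex <- ifelse(d$sex == "female", "male", "female")
  i2 <- interaction_test(d2, "biomarker", "sex")
  expect_equal(i1$beta, -i2$beta, tolerance = 1e-10)
  expect_lt(i1$p, 0.05)  # planted moderation is detected here

  # age moderator with centering
  i3 <- interaction_test(d, "biomarker", "age")
  expect_true(is.finite(i3$beta) && is.finite(i3$p))
  d$sex <- "female"
  expect_error(interaction_test(d, "biomarker", "sex"), "constant")
})

test_that("BH q-values match the step-up definition", {
  expect_equal(as.numeric(fdr_correct(c(0.01, 0.02, 0.04, 0.05))),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(as.numeric(fdr_correct(rep(0.03, 7))), rep(0.03, 7))
  expect_error(fdr_correct(c(0.5, 1.2)), "outside")

  # brute-force oracle on many random vectors
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m); out[o] <- pmin(q, 1)
    out
  }
  set.seed(6)
  for (i in 1:1000) {
    p <- runif(sample(3:40, 1))
    q <- as.numeric(fdr_correct(p))
    expect_identical(all.equal(q, bh_oracle(p), tolerance = 1e-12), TRUE)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("extreme-delta selection uses interpolation percentiles", {
  sel <- select_extreme_deltas(1:20)
  expect_equal(which(sel), c(1, 2, 19, 20))
  # symmetric distribution: equal expected tails
  set.seed(7)
  d <- rnorm(1000)
  sel2 <- select_extreme_deltas(d)
  expect_equal(sum(d[sel2] < 0), sum(d[sel2] > 0), tolerance = 10)
  expect_warning(select_extreme_deltas(rep(1, 30)), "degenerate")
  expect_error(select_extreme_deltas(1:5), "fewer than 10")
})

test_that("the battery enumerates strata x specs and applies one FDR", {
  ds <- small_dataset()
  pipe <- brainage_pipeline(ds, "TRAIN",
                            hyperparams_by_sex = list(female = tiny_hp(),
                                                      male = tiny_hp()),
                            seed = 2)
  res <- run_battery(pipe$analysis)
  expect_true(all(c("stratum", "predictor", "beta", "p", "q", "n") %in%
                    names(res)))
  expect_equal(attr(res, "family_size"), nrow(res))
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$n > 3))
  # skips are logged, not fatal
  expect_type(attr(res, "skipped"), "character")
  # CI contains beta
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
})

test_that("APOE genotypes collapse to the four analysis categories", {
  expect_equal(apoe_category(c("e33", "e22", "e23", "e34", "e44", "e24")),
               c("e33", "e2", "e2", "e4", "e4", "e24"))
  expect_error(apoe_category("e55"), "unknown genotype")
})
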