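test_that("amyloid status applies cohort cut-offs with strict bounds", {
  ct <- load_cutoffs()
  expect_setequal(ct$cohort, c("ALFA+", "EPAD", "ADNI", "OASIS"))

  # CSF: below cut-off is abnormal
  expect_equal(abeta_status(1000, "ALFA+", ct), "A+")
  expect_equal(abeta_status(1100, "ALFA+", ct), "A-")
  expect_equal(abeta_status(879, "ADNI", ct), "A+")
  # boundary values are normal (strict inequality)
  expect_equal(abeta_status(1098, "ALFA+", ct), "A-")
  expect_equal(abeta_status(880, "ADNI", ct), "A-")
  # PET: above cut-off is abnormal; negatives pass through
  expect_equal(abeta_status(20, "OASIS", ct), "A+")
  expect_equal(abeta_status(17, "OASIS", ct), "A-")
  expect_equal(abeta_status(-5, "OASIS", ct), "A-")

  expect_error(abeta_status(1000, "NOPE", ct), "unknown cohort")
  expect_error(abeta_status(-10, "ALFA+", ct), "negative CSF")
  expect_equal(abeta_status(NA, "ALFA+", ct), NA_character_)
})

test_that("AT stages cross amyloid and tau statuses", {
  ct <- load_cutoffs()
  expect_equal(at_stage("A+", 30, "ALFA+", ct), "A+T+")
  expect_equal(at_stage("A-", 10, "ALFA+", ct), "A-T-")
  expect_equal(at_stage("A-", 30, "ALFA+", ct), "A-T+")
  expect_equal(at_stage("A+", 24, "ALFA+", ct), "A+T-")  # boundary: T-
  expect_equal(at_stage("A+", NA, "ALFA+", ct), NA_character_)
})

test_that("A-T+ subjects are excluded with a per-cohort report", {
  tb <- data.frame(cohort = c("X", "X", "Y", "X"),
                   at_stage = c("A-T-", "A+T-", "A-T+", "A+T+"))
  out <- exclude_non_ad_change(tb)
  expect_equal(nrow(out), 3)
  expect_false("A-T+" %in% out$at_stage)
  expect_equal(as.integer(attr(out, "exclusion_report")["Y"]), 1L)

  none <- exclude_non_ad_change(tb[tb$at_stage != "A-T+", ])
  expect_equal(nrow(none), 3)

  # generator-induced A-T+ rate falls inside the binomial 99% CI of a
  # large Monte-Carlo estimate of the same configuration
  cfg <- sim_config(n_subjects = c(S = 2000L), n_regions = 4L, seed = 77L)
  ds <- generate_cohort(cfg)
  ct <- load_cutoffs()
  staged <- stage_biomarkers(ds$biomarkers, rep("ALFA+", 2000), ct)
  rate <- mean(staged$at_stage == "A-T+")
  big <- generate_cohort(sim_config(n_subjects = c(S = 40000L),
                                    n_regions = 4L, seed = 78L))
  pstar <- mean(stage_biomarkers(big$biomarkers,
                                 rep("ALFA+", 40000), ct)$at_stage ==
                  "A-T+")
  ci <- pstar + c(-1, 1) * qnorm(0.995) * sqrt(pstar * (1 - pstar) / 2000)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("aging signature composite is a weighted mean", {
  w <- aging_signature_weights()
  expect_length(w, 8)
  # constant thickness: composite equals the constant
  th <- setNames(rep(2.5, length(w)), names(w))
  expect_equal(aging_signature(th, w), 2.5)
  # hand arithmetic
  expect_equal(aging_signature(setNames(c(2, 3), c("a", "b")),
                               c(a = 1, b = 3)), 2.75)
  # brute-force loop oracle on a random 7-ROI fixture
  set.seed(40)
  th7 <- setNames(runif(7, 2, 3), paste0("roi", 1:7))
  w7 <- setNames(runif(7, 500, 7000), paste0("roi", 1:7))
  loop <- 0; tot <- 0
  for (i in 1:7) { loop <- loop + w7[i] * th7[i]; tot <- tot + w7[i] }
  expect_equal(aging_signature(th7, w7), unname(loop / tot),
               tolerance = 1e-12)
  # composite bounded by its inputs
  expect_true(aging_signature(th7, w7) >= min(th7) &&
                aging_signature(th7, w7) <= max(th7))
  expect_error(aging_signature(th7[1:5], w7), "missing signature ROI")
  expect_error(aging_signature(th7, w7 * 0))
})

test_that("signature z-score and longitudinal change", {
  expect_equal(signature_zscore(2.4, 2.4, 0.1), 0)
  expect_equal(signature_zscore(2.5, 2.4, 0.1), 1)
  expect_error(signature_zscore(2.5, 2.4, 0), "SD")

  expect_equal(signature_change(2.5, 2.5, 3), 0)
  expect_equal(signature_change(2.40, 2.34, 3), -0.02)
  expect_equal(signature_change(2.34, 2.40, 3),
               -signature_change(2.40, 2.34, 3))
  expect_error(signature_change(2.4, 2.3, 0), "interval")
})

test_that("NfL transform is a within-cohort z of the natural log", {
  v <- c(exp(1), exp(2), exp(3))
  z <- transform_nfl(v, rep("A", 3))
  expect_equal(z, c(-1, 0, 1))

  set.seed(41)
  v2 <- c(rlnorm(20, log(10), 0.3), rlnorm(30, log(1000), 0.4))
  co <- rep(c("P", "Q"), c(20, 30))
  z2 <- transform_nfl(v2, co)
  for (c_ in c("P", "Q")) {
    expect_lt(abs(mean(z2[co == c_])), 1e-12)
    expect_equal(sd(z2[co == c_]), 1, tolerance = 1e-12)
    expect_equal(order(z2[co == c_]), order(v2[co == c_]))  # monotone
  }
  expect_error(transform_nfl(c(1, -2), c("A", "A")), "non-positive")
})

test_that("WMH preparation residualizes log volume on TIV", {
  set.seed(42)
  tiv <- rnorm(50, 1500, 100)
  # log-volume exactly linear in TIV -> zero residuals
  wmh <- exp(1 + 0.002 * tiv)
  expect_lt(max(abs(prepare_wmh(wmh, tiv))), 1e-10)

  # matches a brute-force OLS oracle
  wmh2 <- rlnorm(50, log(4000), 0.8)
  des <- cbind(1, tiv)
  beta <- solve(t(des) %*% des, t(des) %*% log(wmh2))
  expect_equal(prepare_wmh(wmh2, tiv), as.numeric(log(wmh2) - des %*% beta),
               tolerance = 1e-10)
  # doubling all volumes only moves the intercept: residuals unchanged
  expect_equal(prepare_wmh(2 * wmh2, tiv), prepare_wmh(wmh2, tiv),
               tolerance = 1e-10)
  expect_error(prepare_wmh(c(0, 1), c(1500, 1500)), "non-positive")
})

test_that("staging a panel is row-permutation equivariant", {
  ds <- generate_cohort(sim_config(n_subjects = c(S = 100L),
                                   n_regions = 4L, seed = 12L))
  ct <- load_cutoffs()
  co <- rep(c("ALFA+", "ADNI"), 50)
  s1 <- stage_biomarkers(ds$biomarkers, co, ct)
  perm <- sample(100)
  s2 <- stage_biomarkers(ds$biomarkers[perm, ], co[perm], ct)
  expect_equal(s2$at_stage, s1$at_stage[perm])
  # the four stages partition the complete cases
  expect_true(all(s1$at_stage %in% c("A-T-", "A+T-", "A+T+", "A-T+")))
})
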