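test_that("simulated cohorts are reproducible and carry provenance", {
  p <- study_ace()
  a <- simulate_univariate_cohort(p, 50, 40, seed = 3)
  b <- simulate_univariate_cohort(p, 50, 40, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_univariate_cohort(p, 50, 40, seed = 4)
  expect_false(identical(a$y_t1, c$y_t1))
  prov <- cohort_provenance(a)
  expect_equal(prov$seed, 3)
  expect_equal(prov$params$a, p$a)
  expect_equal(nrow(a), 180)
  expect_equal(sum(a$zygosity == "MZ"), 100)
})

test_that("zero-pair requests give an empty cohort", {
  empty <- simulate_univariate_cohort(study_ace(), 0, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_univariate_cohort(study_ace(), -1, 0, seed = 1))
})

test_that("sample moments match the implied pair covariance", {
  p <- ace_params(sqrt(0.56), sqrt(0.26), sqrt(0.18))
  coh <- simulate_univariate_cohort(p, 1e5, 1e5, seed = 12)
  pm <- pair_matrix(coh, "y_t1")
  se_r <- (1 - 0.82^2) / sqrt(1e5)  # MC error of a correlation
  expect_equal(cor(pm$MZ)[1, 2], 0.82, tolerance = 3 * se_r / 0.82)
  expect_equal(cor(pm$DZ)[1, 2], 0.54, tolerance = 4 * se_r / 0.54)
  expect_equal(var(as.vector(pm$MZ)), 1, tolerance = 0.02)
})

test_that("sibling interaction inflates variances as the diagonal predicts", {
  base <- ace_params(1, 0, 0.5, s = 0)
  inter <- ace_params(1, 0, 0.5, s = 0.17)
  coh0 <- simulate_univariate_cohort(base, 4e4, 4e4, seed = 5)
  coh1 <- simulate_univariate_cohort(inter, 4e4, 4e4, seed = 5)
  for (z in c("MZ", "DZ")) {
    v0 <- var(as.vector(pair_matrix(coh0, "y_t1")[[z]]))
    v1 <- var(as.vector(pair_matrix(coh1, "y_t1")[[z]]))
    ratio_pred <- pair_covariance(inter, z)[1, 1] /
      pair_covariance(base, z)[1, 1]
    expect_equal(v1 / v0, ratio_pred, tolerance = 0.02)
  }
  # interaction makes MZ and DZ total variances differ
  vmz <- pair_covariance(inter, "MZ")[1, 1]
  vdz <- pair_covariance(inter, "DZ")[1, 1]
  expect_gt(vmz, vdz)
})

test_that("longitudinal generator matches its implied 4x4 covariance", {
  cp <- cholesky_params(a1 = 0.55, ab = 0.33, au = 0.67,
                        c1 = 0.78, cb = 0.26, cu = 0.44,
                        e1 = 0.30, eb = 0.07, eu = 0.42)
  coh <- simulate_longitudinal_cohort(cp, 5e4, 5e4, seed = 21)
  pm <- pair_matrix(coh, c("y_t1", "y_t2"))
  for (z in c("MZ", "DZ"))
    expect_equal(cov(pm[[z]]), implied_covariance_4x4(cp, z),
                 tolerance = 0.03)
  # marginal per-timepoint covariances equal the univariate totals
  t1_tot <- ace_params(cp$a1, cp$c1, cp$e1)
  t2_tot <- ace_params(sqrt(cp$ab^2 + cp$au^2), sqrt(cp$cb^2 + cp$cu^2),
                       sqrt(cp$eb^2 + cp$eu^2))
  for (z in c("MZ", "DZ")) {
    S <- implied_covariance_4x4(cp, z)
    expect_equal(S[1:2, 1:2], pair_covariance(t1_tot, z))
    expect_equal(S[3:4, 3:4], pair_covariance(t2_tot, z))
  }
})

test_that("no carryover means vanishing cross-time sample correlation", {
  cp <- cholesky_params(a1 = 0.6, ab = 0, au = 0.6, e1 = 0.8, eb = 0,
                        eu = 0.8)
  coh <- simulate_longitudinal_cohort(cp, 2e4, 2e4, seed = 8)
  pm <- pair_matrix(coh, c("y_t1", "y_t2"))
  expect_equal(cor(pm$MZ)[1, 3], 0, tolerance = 0.02)
  expect_equal(cor(pm$DZ)[1, 4], 0, tolerance = 0.02)
})

test_that("attach_covariates simulates at the right level and shifts phenotypes", {
  coh <- simulate_univariate_cohort(study_ace(), 300, 300, seed = 2)
  # zero effects leave phenotypes unchanged
  c0 <- attach_covariates(coh, effects = c(income = 0), seed = 9)
  expect_equal(c0$y_t1, coh$y_t1)
  expect_true(all(c("income", "birthweight", "daylight") %in% names(c0)))
  # pair-level covariates identical within pair; twin-level not
  per_pair <- tapply(c0$income, c0$pair_id, function(x) length(unique(x)))
  expect_true(all(per_pair == 1))
  bw_pair <- tapply(c0$birthweight, c0$pair_id,
                    function(x) length(unique(x)))
  expect_true(any(bw_pair > 1))
  expect_error(attach_covariates(coh, effects = c(nonsense = 1)),
               "configuration error")
})

test_that("a strong pair-level covariate inflates MZ and DZ correlations alike", {
  p <- ace_params(0, 0, 1)  # independent twins
  coh <- simulate_univariate_cohort(p, 2e4, 2e4, seed = 31)
  shifted <- attach_covariates(coh, effects = c(income = 2), seed = 32)
  pm <- pair_matrix(shifted, "y_t1")
  r_mz <- cor(pm$MZ)[1, 2]; r_dz <- cor(pm$DZ)[1, 2]
  # pair-level variance acts like shared environment: 4/(4+1) = 0.8
  expect_equal(r_mz, 0.8, tolerance = 0.03)
  expect_equal(r_dz, 0.8, tolerance = 0.03)
  expect_equal(r_mz, r_dz, tolerance = 0.03)
})

test_that("rendered questionnaires round-trip through the parser", {
  coh <- simulate_univariate_cohort(study_ace(), 100, 100, seed = 6)
  raw <- render_questionnaire(coh, seed = 7)  # all artifact rates zero
  parsed <- parse_questionnaire(raw)
  truth <- round(qexp(pnorm(coh$y_t1), rate = 1 / 20), 2)
  expect_equal(parsed$cohort$y_t1, truth)
  expect_true(all(parsed$parse_report$y_t1[c("range_mean", "verbal",
                                             "excluded_ambiguous")] == 0))
})

test_that("range answers parse to the unbiased midpoint, verbal to 2 minutes", {
  coh <- simulate_univariate_cohort(study_ace(), 150, 150, seed = 13)
  raw <- render_questionnaire(coh, artifact_rates = list(range = 1),
                              seed = 14)
  parsed <- parse_questionnaire(raw)
  truth <- round(qexp(pnorm(coh$y_t1), rate = 1 / 20), 2)
  expect_equal(parsed$cohort$y_t1, truth)  # symmetric ranges: midpoint exact
  rawv <- render_questionnaire(coh, artifact_rates = list(verbal = 1),
                               seed = 15)
  parsedv <- parse_questionnaire(rawv)
  expect_true(all(parsedv$cohort$y_t1 == 2))
  expect_error(render_questionnaire(coh, artifact_rates = list(range = 1.4)),
               "configuration error")
})
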