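test_that("Falconer estimates follow the method-of-moments formulas", {
  expect_equal(falconer_estimates(0.91, 0.76),
               c(A = 0.30, C = 0.61, E = 0.09))
  expect_equal(falconer_estimates(0.82, 0.54),
               c(A = 0.56, C = 0.26, E = 0.18))
  expect_equal(falconer_estimates(0.4, 0.4), c(A = 0, C = 0.4, E = 0.6))
  # raw method-of-moments values are not truncated to [0, 1]
  expect_gt(falconer_estimates(0.1, 0.7)[["C"]], 1)
  expect_lt(falconer_estimates(0.1, 0.7)[["A"]], 0)
  expect_lt(falconer_estimates(0.9, 0.1)[["C"]], 0)
})

test_that("ML on moment-exact data reproduces the Falconer solution", {
  coh <- make_exact_correlation_cohort(0.91, 0.76, seed = 2)
  fit <- fit_variance_components(coh, "y_t1", model = "ACE")
  expect_equal(unname(fit$std),
               unname(falconer_estimates(0.91, 0.76)), tolerance = 1e-4)
  expect_true(fit$converged)
  # complete-data saturated estimates equal the sample moments
  sat <- fit_saturated(coh, "y_t1")
  expect_equal(sat$moments$MZ$Sigma[1, 2], 0.91, tolerance = 1e-5)
  expect_equal(diag(sat$moments$DZ$Sigma), c(1, 1), tolerance = 1e-5)
  # structured -2LL can never beat the saturated one
  expect_gte(fit$minus2LL, sat$minus2LL - 1e-6)
})

test_that("implied twin correlations invert the ACE structure", {
  expect_equal(implied_twin_correlations(c(A = 0.56, C = 0.26)),
               c(r_mz = 0.82, r_dz = 0.54))
  expect_equal(implied_twin_correlations(c(A = 0, C = 0)),
               c(r_mz = 0, r_dz = 0))
  # with interaction, matches the Monte-Carlo correlation of the generator
  p <- ace_params(sqrt(0.48), 0, sqrt(0.52), s = 0.17)
  coh <- simulate_univariate_cohort(p, 1e5, 1e5, seed = 44)
  fit <- fit_variance_components(coh, "y_t1", model = "AE", with_s = TRUE)
  r <- implied_twin_correlations(fit)
  pm <- pair_matrix(coh, "y_t1")
  expect_equal(unname(r["r_mz"]), cor(pm$MZ)[1, 2], tolerance = 0.01)
  expect_equal(unname(r["r_dz"]), cor(pm$DZ)[1, 2], tolerance = 0.01)
})

test_that("generating components are recovered with small bias across families", {
  # Bias = mean estimate minus truth over fixed-seed replicates at
  # 5,000 pairs per zygosity; the tolerance covers |bias| < 0.02 plus
  # the Monte-Carlo error of the replicate mean.
  n <- 5000
  cases <- list(
    list(model = "ACE", p = ace_params(sqrt(0.3), sqrt(0.4), sqrt(0.3))),
    list(model = "ACE", p = ace_params(sqrt(0.6), sqrt(0.2), sqrt(0.2))),
    list(model = "ACE", p = ace_params(sqrt(0.1), sqrt(0.6), sqrt(0.3))),
    list(model = "AE",  p = ace_params(sqrt(0.5), 0, sqrt(0.5))),
    list(model = "CE",  p = ace_params(0, sqrt(0.6), sqrt(0.4))),
    list(model = "E",   p = ace_params(0, 0, 1)))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    est <- sapply(1:3, function(r) {
      coh <- simulate_univariate_cohort(cs$p, n, n, seed = 300 + 10 * i + r)
      fit_variance_components(coh, "y_t1", model = cs$model)$std
    })
    tot <- cs$p$a^2 + cs$p$c^2 + cs$p$e^2
    truth <- c(A = cs$p$a^2, C = cs$p$c^2, E = cs$p$e^2) / tot
    expect_lt(max(abs(rowMeans(est) - truth)), 0.025)
  }
})

test_that("the ACE-s estimator has small bias despite exact identification", {
  # With one timepoint ACE-s is exactly identified from four moments,
  # so single-replicate estimates of C and s are noisy; the bias of the
  # estimator over replicates stays small. Tolerances are |bias| < 0.02
  # plus ~2 Monte-Carlo standard errors of the replicate mean.
  p <- ace_params(sqrt(0.3), sqrt(0.4), sqrt(0.3), s = 0.15)
  est <- sapply(1:24, function(r) {
    coh <- simulate_univariate_cohort(p, 5000, 5000, seed = 1300 + r)
    f <- fit_variance_components(coh, "y_t1", model = "ACE",
                                 with_s = TRUE)
    c(f$std, s = f$s)
  })
  m <- rowMeans(est)
  expect_lt(max(abs(m[c("A", "C", "E")] - c(0.3, 0.4, 0.3))), 0.08)
  expect_lt(abs(m[["s"]] - 0.15), 0.06)
  # the ACE-s fit constrained to s = 0 reproduces the plain ACE fit
  coh <- simulate_univariate_cohort(p, 500, 500, seed = 1399)
  ace <- fit_variance_components(coh, "y_t1", model = "ACE")
  aces <- fit_variance_components(coh, "y_t1", model = "ACE",
                                  with_s = TRUE)
  expect_lte(aces$minus2LL, ace$minus2LL + 1e-6)
  expect_equal(twinkit:::profiled_min(aces, s_fix = 0), ace$minus2LL,
               tolerance = 1e-6)
})

test_that("the -2LL respects nesting order on any dataset", {
  for (seed in c(9, 10)) {
    coh <- simulate_univariate_cohort(
      ace_params(sqrt(0.4), sqrt(0.3), sqrt(0.3)), 150, 150, seed = seed)
    m2 <- sapply(c("E", "CE", "AE", "ACE"), function(m)
      fit_variance_components(coh, "y_t1", model = m)$minus2LL)
    expect_gte(m2[["E"]], m2[["CE"]] - 1e-6)
    expect_gte(m2[["E"]], m2[["AE"]] - 1e-6)
    expect_gte(m2[["CE"]], m2[["ACE"]] - 1e-6)
    expect_gte(m2[["AE"]], m2[["ACE"]] - 1e-6)
  }
})

test_that("standardized components are invariant to affine rescaling", {
  coh <- simulate_univariate_cohort(
    ace_params(sqrt(0.5), sqrt(0.3), sqrt(0.2)), 400, 400, seed = 23)
  scaled <- as.data.frame(coh)
  scaled$y_t1 <- 13.5 + 4.2 * scaled$y_t1
  scaled <- twin_cohort(scaled, "y", "t1")
  f1 <- fit_variance_components(coh, "y_t1", model = "ACE")
  f2 <- fit_variance_components(scaled, "y_t1", model = "ACE")
  expect_equal(f1$std, f2$std, tolerance = 1e-5)
  ci1 <- profile_ci(f1, "A")
  ci2 <- profile_ci(f2, "A")
  expect_equal(ci1, ci2, tolerance = 1e-3)
})

test_that("ACE-s at s = 0 behaves as a null extension of ACE", {
  coh <- simulate_univariate_cohort(
    ace_params(sqrt(0.4), sqrt(0.35), sqrt(0.25)), 242, 218, seed = 29)
  f0 <- fit_variance_components(coh, "y_t1", model = "ACE")
  fs <- fit_variance_components(coh, "y_t1", model = "ACE", with_s = TRUE)
  expect_lte(fs$minus2LL, f0$minus2LL + 1e-6)
  expect_lt(f0$minus2LL - fs$minus2LL, qchisq(0.999, 1))
  # s-hat near 0 relative to its profile CI
  ci <- profile_ci(fs, "s")
  expect_lt(ci[["lower"]], 0)
  expect_gt(ci[["upper"]], 0)
})

test_that("model comparison does the chi-squared bookkeeping", {
  coh <- simulate_univariate_cohort(study_ace(), 120, 120, seed = 31)
  ace <- fit_variance_components(coh, "y_t1", model = "ACE")
  ae <- fit_variance_components(coh, "y_t1", model = "AE")
  cmp <- compare_models(ae, ace)
  expect_equal(cmp$delta_chi2, ae$minus2LL - ace$minus2LL,
               tolerance = 1e-8)
  expect_equal(cmp$delta_df, 1)
  expect_equal(cmp$p, pchisq(cmp$delta_chi2, 1, lower.tail = FALSE))
  # identical models: zero chi-squared, p = 1
  cmp0 <- compare_models(ace, ace)
  expect_equal(cmp0$delta_chi2, 0)
  expect_equal(cmp0$p, 1)
  expect_error(compare_models(ace, ae), "not nested")
  # AIC bookkeeping on the fit objects themselves
  expect_equal(ace$aic, ace$minus2LL + 2 * 4)
  expect_equal(ae$aic, ae$minus2LL + 2 * 3)
})

test_that("model selection minimizes AIC among adequate fits, deterministically", {
  coh <- simulate_univariate_cohort(
    ace_params(0, sqrt(0.6), sqrt(0.4)), 1000, 1000, seed = 37)
  fits <- lapply(c(E = "E", CE = "CE", AE = "AE", ACE = "ACE"),
                 function(m) fit_variance_components(coh, "y_t1", model = m))
  ref <- fit_variance_components(coh, "y_t1", model = "ACE", with_s = TRUE)
  sel <- select_model(fits, ref)
  expect_equal(sel$model, "CE")  # generating family at large n
  expect_s3_class(attr(sel, "selection"), "data.frame")
  # one candidate: itself
  expect_equal(select_model(fits["CE"], ref)$model, "CE")
  # AIC ties break to fewer parameters
  f_a <- fits$CE; f_b <- fits$ACE
  f_b$aic <- f_a$aic  # force a tie
  expect_equal(select_model(list(f_a, f_b), ref)$model, "CE")
})

test_that("saturated assumption tests detect zygosity variance differences", {
  # s > 0 generator inflates MZ variance relative to DZ
  p <- ace_params(sqrt(0.5), 0, sqrt(0.5), s = 0.2)
  hits <- 0
  for (i in 1:10) {
    coh <- simulate_univariate_cohort(p, 5000, 5000, seed = 400 + i)
    sat <- fit_saturated(coh, "y_t1")
    tst <- sat$assumption_tests
    if (tst$p[tst$test == "equal variances across zygosity"] < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / 10, 0.8)
  # null generator: tests non-significant at roughly nominal rates
  p0 <- study_ace()
  ps <- sapply(1:15, function(i) {
    coh <- simulate_univariate_cohort(p0, 200, 200, seed = 550 + i)
    min(fit_saturated(coh, "y_t1")$assumption_tests$p)
  })
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("single-twin pairs contribute through the marginal likelihood", {
  coh <- simulate_univariate_cohort(study_ace(), 300, 300, seed = 43)
  df <- as.data.frame(coh)
  # drop twin 2 of a third of the pairs
  drop <- df$twin_order == 2 & (match(df$pair_id, unique(df$pair_id)) %% 3 == 0)
  df$y_t1[drop] <- NA
  coh_m <- twin_cohort(df, "y", "t1")
  fit_m <- fit_variance_components(coh_m, "y_t1", model = "ACE")
  fit_c <- fit_variance_components(coh, "y_t1", model = "ACE")
  expect_true(fit_m$converged)
  expect_equal(fit_m$std, fit_c$std, tolerance = 0.1)
  # removed rows reduce the likelihood magnitude
  expect_lt(fit_m$minus2LL, fit_c$minus2LL)
})

test_that("twin correlations match the double-entry estimator and bracket truth", {
  coh <- simulate_univariate_cohort(
    ace_params(sqrt(0.56), sqrt(0.26), sqrt(0.18)), 4000, 4000, seed = 47)
  tc <- twin_correlations(coh, "y_t1")
  pm <- pair_matrix(coh, "y_t1")
  expect_equal(tc$r[tc$zygosity == "MZ"], double_entry_cor(pm$MZ),
               tolerance = 2e-3)
  expect_equal(tc$r[tc$zygosity == "DZ"], double_entry_cor(pm$DZ),
               tolerance = 2e-3)
  expect_equal(tc$r[tc$zygosity == "MZ"], 0.82, tolerance = 0.02)
  expect_true(all(tc$lower < tc$r & tc$r < tc$upper))
  # independent twins: correlation near zero
  coh0 <- simulate_univariate_cohort(ace_params(0, 0, 1), 500, 500,
                                     seed = 48)
  tc0 <- twin_correlations(coh0, "y_t1", ci = FALSE)
  expect_lt(max(abs(tc0$r)), 0.1)
})

test_that("profile intervals behave at boundaries and cover the estimate", {
  coh <- make_exact_correlation_cohort(0.91, 0.76, seed = 3)
  fit <- fit_variance_components(coh, "y_t1", model = "ACE")
  for (comp in c("A", "C", "E")) {
    ci <- profile_ci(fit, comp)
    expect_lt(ci[["lower"]], fit$std[[comp]])
    expect_gt(ci[["upper"]], fit$std[[comp]])
    expect_gte(ci[["lower"]], 0)
    expect_lte(ci[["upper"]], 1)
  }
  # a component absent from the family has a degenerate interval
  ae <- fit_variance_components(coh, "y_t1", model = "AE")
  expect_equal(unname(profile_ci(ae, "C")), c(0, 0))
  e_only <- fit_variance_components(coh, "y_t1", model = "E")
  expect_equal(unname(profile_ci(e_only, "E")), c(1, 1))
})
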