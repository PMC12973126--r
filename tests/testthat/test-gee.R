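test_that("with singleton clusters GEE reduces to OLS with HC0 errors", {
  set.seed(101)
  n <- 150
  x <- rnorm(n)
  y <- 2 - 0.7 * x + rnorm(n) * (1 + 0.5 * abs(x))
  X <- cbind(intercept = 1, x = x)
  fit <- fit_gee(y, X, cluster_ids = seq_len(n),
                 working_structure = "independence")
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$robust_covariance,
               unname(sandwich::vcovHC(ols, type = "HC0")),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("sandwich covariance approaches the classical OLS covariance under iid errors", {
  set.seed(33)
  n <- 1e4
  x <- rnorm(n)
  y <- 1 + 0.3 * x + rnorm(n)
  X <- cbind(1, x)
  fit <- fit_gee(y, X, seq_len(n), working_structure = "independence")
  ols <- stats::lm(y ~ x)
  expect_equal(diag(fit$robust_covariance), diag(stats::vcov(ols)),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("GEE is invariant to cluster relabeling and row order", {
  coh <- attach_covariates(
    simulate_univariate_cohort(study_ace(), 80, 80, seed = 17),
    effects = c(birthweight = 0.3), seed = 18)
  X <- cbind(1, bw = coh$birthweight)
  f1 <- fit_gee(coh$y_t1, X, coh$pair_id)
  perm <- sample(nrow(coh))
  f2 <- fit_gee(coh$y_t1[perm], X[perm, ], coh$pair_id[perm])
  relab <- match(coh$pair_id, unique(coh$pair_id)) * 7 + 3
  f3 <- fit_gee(coh$y_t1, X, relab)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$robust_covariance, f3$robust_covariance,
               tolerance = 1e-8)
})

test_that("GEE recovers a known twin-level effect with near-nominal CI coverage", {
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    coh <- attach_covariates(
      simulate_univariate_cohort(study_ace(), 100, 100, seed = 4000 + i),
      effects = c(birthweight = 0.2), seed = 5000 + i)
    zx <- as.numeric(scale(coh$birthweight))
    fit <- fit_gee(coh$y_t1, cbind(1, x = zx), coh$pair_id)
    if (abs(fit$coefficients[["x"]] - 0.2) <= 2 * fit$se[["x"]])
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("degenerate designs error clearly", {
  y <- rnorm(10); X <- cbind(1, rep(2, 10))
  expect_error(fit_gee(y, X, rep(1:5, each = 2)), "singular design")
  expect_error(fit_gee(rnorm(4), cbind(1, rnorm(4)), rep(1, 4)),
               "degenerate variance")
})

test_that("covariate screening flags real effects and handles edge cases", {
  coh <- attach_covariates(
    simulate_univariate_cohort(study_ace(), 242, 218, seed = 51),
    effects = c(daylight = 0.3), seed = 52)
  tab <- screen_covariates(coh, "y_t1",
                           c("daylight", "income", "birthweight"))
  expect_true(tab$flagged[tab$variable == "daylight"])
  # pair-constant covariate fits without error (income is pair-level)
  expect_true(all(is.finite(tab$z)))
  # constant covariate skipped with warning
  coh2 <- as.data.frame(coh); coh2$const <- 1
  coh2 <- twin_cohort(coh2, "y", "t1")
  expect_warning(out <- screen_covariates(coh2, "y_t1",
                                          c("const", "income")),
                 "constant")
  expect_equal(out$variable, "income")
})

test_that("null covariates are flagged at close to the nominal rate", {
  set.seed(61)
  flags <- 0; m <- 0
  for (i in 1:40) {
    coh <- attach_covariates(
      simulate_univariate_cohort(study_ace(), 100, 100, seed = 6000 + i),
      seed = 7000 + i)
    tab <- screen_covariates(coh, "y_t1",
                             c("income", "birthweight", "maternal_age"))
    flags <- flags + sum(tab$flagged); m <- m + nrow(tab)
  }
  expect_lt(abs(flags / m - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("residualization is mean-zero, idempotent, and effect-removing", {
  coh <- attach_covariates(
    simulate_univariate_cohort(study_ace(), 3000, 3000, seed = 71),
    effects = c(income = 0.5), seed = 72)
  res <- residualize(coh, "y_t1", c("sex", "income"))
  expect_equal(mean(res$y_t1_resid, na.rm = TRUE), 0, tolerance = 1e-8)
  # twice is a no-op
  res2 <- residualize(res, "y_t1_resid", c("sex", "income"))
  expect_equal(res2$y_t1_resid_resid, res$y_t1_resid, tolerance = 1e-6)
  # residual twin correlations match a covariate-free generator
  clean <- simulate_univariate_cohort(study_ace(), 3000, 3000, seed = 71)
  r_res <- cor(pair_matrix(res, "y_t1_resid")$MZ)[1, 2]
  r_clean <- cor(pair_matrix(clean, "y_t1")$MZ)[1, 2]
  expect_equal(r_res, r_clean, tolerance = 0.01)
  # zero-effect covariate: residual equals the centered phenotype
  res0 <- residualize(clean, "y_t1", character(0))
  expect_equal(res0$y_t1_resid, clean$y_t1 - mean(clean$y_t1))
})

test_that("PGS association is null-calibrated, standardized, and scale-invariant", {
  coh <- simulate_univariate_cohort(study_ace(), 242, 218, seed = 81)
  df <- as.data.frame(coh)
  set.seed(82)
  pairs <- unique(df$pair_id)
  score_pair <- rnorm(length(pairs))
  df$score <- score_pair[match(df$pair_id, pairs)] + rnorm(nrow(df), sd = 0.3)
  for (k in 1:10) df[[paste0("pc", k)]] <- rnorm(nrow(df))
  coh <- twin_cohort(df, "y", "t1")
  fit <- pgs_association(coh, "score", "y_t1", n_pcs = 10)
  expect_lt(abs(fit$coefficients[["score"]]), 2 * fit$se[["score"]])
  # affine rescaling of the raw score leaves the standardized beta alone
  df$score <- 100 + 42 * df$score
  fit2 <- pgs_association(twin_cohort(df, "y", "t1"), "score", "y_t1")
  expect_equal(fit$coefficients[["score"]], fit2$coefficients[["score"]],
               tolerance = 1e-10)
  expect_error(pgs_association(coh, "score", "y_t1", n_pcs = 12),
               "configuration error")
})

test_that("a generator with standardized effect 0.16 is recovered on average", {
  betas <- sapply(1:40, function(i) {
    coh <- simulate_univariate_cohort(
      ace_params(sqrt(0.5), 0, sqrt(0.5)), 242, 218, seed = 8000 + i)
    df <- as.data.frame(coh)
    set.seed(9000 + i)
    df$score <- rnorm(nrow(df))
    vy <- 1  # latent variance
    df$y_t1 <- df$y_t1 + 0.16 * sqrt(vy) * df$score
    for (k in 1:10) df[[paste0("pc", k)]] <- rnorm(nrow(df))
    fit <- pgs_association(twin_cohort(df, "y", "t1"), "score", "y_t1")
    fit$coefficients[["score"]]
  })
  # phenotype standardization shrinks beta by sd(y) = sqrt(1 + 0.16^2)
  expect_equal(mean(betas), 0.16 / sqrt(1 + 0.16^2), tolerance = 0.015)
})

test_that("Bonferroni threshold matches the reporting convention", {
  b <- bonferroni_threshold(0.05, 14)
  expect_equal(b$threshold, 0.05 / 14)
  expect_equal(b$rounded, 0.004)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 50)$threshold, 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "invalid input")
})
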