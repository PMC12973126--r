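#' Simulate a univariate twin cohort under the ACE(-s) model
#'
#' Draws zero-mean multivariate-normal pair phenotypes with the exact
#' covariance structure of [pair_covariance()], MZ pairs first and DZ
#' pairs second (one RNG stream, fixed order, so cohorts are
#' bit-reproducible given the seed). Pair sex is assigned alternately
#' (the design has same-sex pairs only, and the latent model is
#' sex-free; covariate effects are added by [attach_covariates()]).
#'
#' @param params an [ace_params()] object.
#' @param n_mz_pairs,n_dz_pairs numbers of MZ and DZ pairs (>= 0).
#' @param seed integer RNG seed.
#' @param phenotype phenotype base name for the generated column,
#'   default `"y"` (column `y_t1`).
#' @return A [twin_cohort()] with provenance recording `params` and
#'   `seed`.
#' @examples
#' coh <- simulate_univariate_cohort(
#'   ace_params(a = sqrt(0.56), c = sqrt(0.26), e = sqrt(0.18)),
#'   n_mz_pairs = 242, n_dz_pairs = 218, seed = 1)
#' @export
simulate_univariate_cohort <- function(params, n_mz_pairs, n_dz_pairs, seed,
                                       phenotype = "y") {
  if (!inherits(params, "ace_params"))
    params <- do.call(ace_params, as.list(params))
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0)
  set.seed(seed)
  blocks <- list()
  for (z in c("MZ", "DZ")) {
    n <- if (z == "MZ") n_mz_pairs else n_dz_pairs
    if (n == 0) next
    Sigma <- pair_covariance(params, z)
    Y <- matrix(stats::rnorm(2L * n), n, 2L) %*% chol(Sigma)
    blocks[[z]] <- data.frame(
      pair_id = sprintf("%s_%04d", tolower(z), seq_len(n)),
      zygosity = z, y1 = Y[, 1], y2 = Y[, 2])
  }
  pairs <- do.call(rbind, blocks)
  col <- paste0(phenotype, "_t1")
  if (is.null(pairs)) {
    data <- data.frame(pair_id = character(), twin_order = integer(),
                       zygosity = character(), sex = character())
    data[[col]] <- numeric()
  } else {
    pairs$sex <- rep_len(c("F", "M"), nrow(pairs))
    data <- data.frame(
      pair_id = rep(pairs$pair_id, each = 2),
      twin_order = rep(1:2, nrow(pairs)),
      zygosity = rep(pairs$zygosity, each = 2),
      sex = rep(pairs$sex, each = 2))
    data[[col]] <- as.vector(rbind(pairs$y1, pairs$y2))
  }
  structure(
    twin_cohort(data, phenotypes = phenotype, timepoints = "t1",
                provenance = list(generator = "simulate_univariate_cohort",
                                  params = unclass(params), seed = seed)),
    class = c("twin_cohort", "data.frame"))
}

#' Simulate a two-timepoint twin cohort under the Cholesky model
#'
#' Each pair contributes a 4-vector (twin1-t1, twin2-t1, twin1-t2,
#' twin2-t2) drawn from the zero-mean multivariate normal with
#' [implied_covariance_4x4()] as covariance; MZ pairs are drawn before
#' DZ pairs in one RNG stream.
#'
#' @param params a [cholesky_params()] object.
#' @inheritParams simulate_univariate_cohort
#' @return A [twin_cohort()] with columns `<phenotype>_t1` and
#'   `<phenotype>_t2`.
#' @export
simulate_longitudinal_cohort <- function(params, n_mz_pairs, n_dz_pairs, seed,
                                         phenotype = "y") {
  if (!inherits(params, "cholesky_params"))
    params <- do.call(cholesky_params, as.list(params))
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0)
  set.seed(seed)
  blocks <- list()
  for (z in c("MZ", "DZ")) {
    n <- if (z == "MZ") n_mz_pairs else n_dz_pairs
    if (n == 0) next
    Sigma <- implied_covariance_4x4(params, z)
    Y <- matrix(stats::rnorm(4L * n), n, 4L) %*% chol(Sigma)
    blocks[[z]] <- data.frame(
      pair_id = sprintf("%s_%04d", tolower(z), seq_len(n)),
      zygosity = z,
      y11 = Y[, 1], y21 = Y[, 2], y12 = Y[, 3], y22 = Y[, 4])
  }
  pairs <- do.call(rbind, blocks)
  c1 <- paste0(phenotype, "_t1"); c2 <- paste0(phenotype, "_t2")
  if (is.null(pairs)) {
    data <- data.frame(pair_id = character(), twin_order = integer(),
                       zygosity = character(), sex = character())
    data[[c1]] <- numeric(); data[[c2]] <- numeric()
  } else {
    pairs$sex <- rep_len(c("F", "M"), nrow(pairs))
    data <- data.frame(
      pair_id = rep(pairs$pair_id, each = 2),
      twin_order = rep(1:2, nrow(pairs)),
      zygosity = rep(pairs$zygosity, each = 2),
      sex = rep(pairs$sex, each = 2))
    data[[c1]] <- as.vector(rbind(pairs$y11, pairs$y21))
    data[[c2]] <- as.vector(rbind(pairs$y12, pairs$y22))
  }
  twin_cohort(data, phenotypes = phenotype, timepoints = c("t1", "t2"),
              provenance = list(generator = "simulate_longitudinal_cohort",
                                params = unclass(params), seed = seed))
}

#' Construct twin data with exact sample correlations
#'
#' Builds per-zygosity pair matrices whose sample means are exactly zero,
#' sample variances (maximum-likelihood denominator, i.e. dividing by n)
#' exactly one, and within-pair sample correlations exactly the requested
#' values. Useful for deterministic worked examples: when the sample
#' moments satisfy the ACE structure exactly, the maximum-likelihood fit
#' reproduces the method-of-moments (Falconer) solution exactly.
#'
#' @param r_mz,r_dz target within-pair correlations, in (-1, 1).
#' @param n_mz_pairs,n_dz_pairs pairs per zygosity (>= 3).
#' @param seed integer seed for the underlying raw draws (the imposed
#'   moments are exact for any seed).
#' @param phenotype phenotype base name, default `"y"`.
#' @return A [twin_cohort()].
#' @export
make_exact_correlation_cohort <- function(r_mz, r_dz, n_mz_pairs = 242,
                                          n_dz_pairs = 218, seed = 1,
                                          phenotype = "y") {
  stopifnot(abs(r_mz) < 1, abs(r_dz) < 1, n_mz_pairs >= 3, n_dz_pairs >= 3)
  set.seed(seed)
  impose <- function(n, r) {
    target <- matrix(c(1, r, r, 1), 2, 2)
    Y0 <- matrix(stats::rnorm(2L * n), n, 2L)
    Y0 <- sweep(Y0, 2, colMeans(Y0))
    C0 <- crossprod(Y0) / n
    Y0 %*% solve(chol(C0)) %*% chol(target)
  }
  Ymz <- impose(n_mz_pairs, r_mz)
  Ydz <- impose(n_dz_pairs, r_dz)
  col <- paste0(phenotype, "_t1")
  data <- data.frame(
    pair_id = c(rep(sprintf("mz_%04d", seq_len(n_mz_pairs)), each = 2),
                rep(sprintf("dz_%04d", seq_len(n_dz_pairs)), each = 2)),
    twin_order = rep(1:2, n_mz_pairs + n_dz_pairs),
    zygosity = c(rep("MZ", 2L * n_mz_pairs), rep("DZ", 2L * n_dz_pairs)),
    sex = rep(rep_len(c("F", "M"), n_mz_pairs + n_dz_pairs), each = 2))
  data[[col]] <- c(as.vector(t(Ymz)), as.vector(t(Ydz)))
  twin_cohort(data, phenotypes = phenotype, timepoints = "t1",
              provenance = list(generator = "make_exact_correlation_cohort",
                                r_mz = r_mz, r_dz = r_dz, seed = seed))
}

#' Attach simulated covariates with known linear effects
#'
#' Simulates background covariates at the appropriate level — shared by
#' both twins of a pair (family income band, parental ages, gestational
#' age, assessment age, daylight exposure) or twin-specific (birthweight)
#' — and shifts every phenotype column by the requested linear effects.
#' Effects are applied to the standardized (z-scored) covariate, so each
#' coefficient is in phenotype units per covariate SD; the covariate is
#' centered before shifting, leaving the phenotype mean unchanged. The
#' effects are recorded in the cohort provenance.
#'
#' Default covariate distributions mirror a Swedish infant-twin cohort:
#' birthweight ~ N(2694, 387) g, gestational age ~ N(36.7, 1.15) weeks
#' truncated to [34, 39], income band uniform on 1..10, maternal age
#' ~ N(31.9, 4.3) y, paternal age ~ N(33.8, 5.5) y, assessment ages
#' ~ N(60, 12) / N(150, 12) days (held inside the +/-40-day windows),
#' and daylight exposure from a random postal region and month via
#' [assign_region_daylight()].
#'
#' @param cohort a [twin_cohort()].
#' @param effects named numeric vector of effects, names in
#'   `c("birthweight", "gestational_age", "income", "maternal_age",
#'   "paternal_age", "daylight", "age")`; covariates named with effect 0
#'   are still simulated and attached.
#' @param seed integer RNG seed (independent of the cohort's phenotype
#'   stream).
#' @param covariates which covariates to attach; defaults to all of the
#'   above.
#' @return The cohort with covariate columns appended and phenotypes
#'   shifted.
#' @export
attach_covariates <- function(cohort, effects = numeric(0), seed = 1,
                              covariates = c("birthweight", "gestational_age",
                                             "income", "maternal_age",
                                             "paternal_age", "daylight",
                                             "age")) {
  known <- c("birthweight", "gestational_age", "income", "maternal_age",
             "paternal_age", "daylight", "age")
  if (length(effects) && (is.null(names(effects)) ||
                          !all(names(effects) %in% known)))
    stop("configuration error: unknown covariate role in 'effects'")
  if (!all(covariates %in% known))
    stop("configuration error: unknown covariate name")
  pheno_cols <- grep("_t[0-9]+$", names(cohort), value = TRUE)
  if (any(covariates %in% sub("_t[0-9]+$", "", pheno_cols)))
    stop("covariate names must be disjoint from phenotype names")
  set.seed(seed)
  pairs <- unique(cohort$pair_id)
  np <- length(pairs)
  pair_val <- function(x) x[match(cohort$pair_id, pairs)]
  sim <- list()
  for (cv in covariates) {
    sim[[cv]] <- switch(cv,
      birthweight = stats::rnorm(nrow(cohort), 2694, 387),
      gestational_age = pair_val(pmin(39, pmax(34, stats::rnorm(np, 36.7, 1.15)))),
      income = pair_val(sample(1:10, np, replace = TRUE)),
      maternal_age = pair_val(stats::rnorm(np, 31.9, 4.3)),
      paternal_age = pair_val(stats::rnorm(np, 33.8, 5.5)),
      daylight = pair_val(assign_region_daylight(
        sample(1:9, np, replace = TRUE), sample(1:12, np, replace = TRUE))),
      age = pair_val(pmin(99, pmax(27, round(stats::rnorm(np, 60, 12))))))
  }
  out <- as.data.frame(cohort)
  for (cv in names(sim)) out[[cv]] <- sim[[cv]]
  for (cv in names(effects)) {
    beta <- effects[[cv]]
    if (beta == 0) next
    x <- sim[[cv]]
    zx <- (x - mean(x)) / stats::sd(x)
    for (col in pheno_cols) out[[col]] <- out[[col]] + beta * zx
  }
  prov <- cohort_provenance(cohort) %||% list()
  prov$covariate_effects <- as.list(effects)
  prov$covariate_seed <- seed
  twin_cohort(out, phenotypes = cohort_phenotypes(cohort),
              timepoints = cohort_timepoints(cohort), provenance = prov)
}

#' Render latent phenotypes as raw questionnaire responses
#'
#' Maps each latent (approximately standard-normal) phenotype cell to a
#' nonnegative duration in minutes through the monotone transform
#' \eqn{m = Q_{exp}(\Phi(z))} (exponential marginal with configurable
#' mean), then writes free-text response strings, injecting configured
#' fractions of questionnaire artifacts: symmetric range answers
#' (`"15–25 min"`, whose midpoint equals the true value), verbal answers
#' (`"a couple of minutes"`), unit-ambiguous small numbers (bare values
#' in (0, 1), which [parse_duration()] excludes), and empty cells. With
#' all artifact rates zero the rendered strings parse back to the
#' underlying minutes exactly.
#'
#' @param cohort a [twin_cohort()] with latent-scale phenotypes.
#' @param artifact_rates named list/vector with elements `range`,
#'   `verbal`, `ambiguous`, `missing`, each a probability; they must sum
#'   to at most 1.
#' @param seed integer RNG seed.
#' @param mean_minutes mean of the exponential duration marginal
#'   (default 20, a typical settle/crying duration).
#' @return A data frame shaped like the cohort, phenotype columns
#'   replaced by character responses.
#' @export
render_questionnaire <- function(cohort,
                                 artifact_rates = list(range = 0, verbal = 0,
                                                       ambiguous = 0,
                                                       missing = 0),
                                 seed = 1, mean_minutes = 20) {
  rates <- c(range = 0, verbal = 0, ambiguous = 0, missing = 0)
  rates[names(artifact_rates)] <- unlist(artifact_rates)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1)
    stop("configuration error: artifact rates must lie in [0,1] and sum to <= 1")
  set.seed(seed)
  out <- as.data.frame(cohort)
  pheno_cols <- grep("_t[0-9]+$", names(out), value = TRUE)
  for (col in pheno_cols) {
    z <- out[[col]]
    minutes <- round(stats::qexp(stats::pnorm(z), rate = 1 / mean_minutes), 2)
    kind <- sample(c("numeric", "range", "verbal", "ambiguous", "missing"),
                   length(minutes), replace = TRUE,
                   prob = c(1 - sum(rates), rates))
    resp <- character(length(minutes))
    for (i in seq_along(minutes)) {
      v <- minutes[i]
      resp[i] <- switch(kind[i],
        numeric = sprintf("%s min", format(v, scientific = FALSE)),
        range = {
          d <- round(v / 2, 2)
          sprintf("%s–%s min",
                  format(round(v - d, 2), scientific = FALSE),
                  format(round(v + d, 2), scientific = FALSE))
        },
        verbal = sample(c("a couple of minutes", "a few minutes"), 1),
        ambiguous = format(round(stats::runif(1, 0.05, 0.95), 2),
                           scientific = FALSE),
        missing = "")
      if (is.na(z[i])) resp[i] <- ""
    }
    out[[col]] <- resp
  }
  out
}
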