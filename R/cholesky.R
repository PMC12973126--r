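# Bivariate (two-timepoint) longitudinal Cholesky decomposition:
# partitions genetic and environmental variance at the second age into
# components carried over from the first age versus age-unique ones.

chol_param_names <- function(family, with_s) {
  comp <- strsplit(family, "")[[1]]
  nm <- unlist(lapply(tolower(comp), function(x) paste0(x, c("1", "b", "u"))))
  if (with_s) nm <- c(nm, "s1", "s2")
  nm
}

# Fast implied 4x4 covariance from a named path vector (zeros for
# dropped components); NULL on a non-PD result.
chol_sigma <- function(p, rho) {
  comp2 <- function(x1, xb, xu)
    matrix(c(x1^2, x1 * xb, x1 * xb, xb^2 + xu^2), 2, 2)
  W <- comp2(p[["a1"]], p[["ab"]], p[["au"]]) +
    comp2(p[["c1"]], p[["cb"]], p[["cu"]]) +
    comp2(p[["e1"]], p[["eb"]], p[["eu"]])
  X <- rho * comp2(p[["a1"]], p[["ab"]], p[["au"]]) +
    comp2(p[["c1"]], p[["cb"]], p[["cu"]])
  S <- matrix(0, 4, 4)
  S[1:2, 1:2] <- matrix(c(W[1, 1], X[1, 1], X[1, 1], W[1, 1]), 2, 2)
  S[3:4, 3:4] <- matrix(c(W[2, 2], X[2, 2], X[2, 2], W[2, 2]), 2, 2)
  cross <- matrix(c(W[1, 2], X[1, 2], X[1, 2], W[1, 2]), 2, 2)
  S[1:2, 3:4] <- cross
  S[3:4, 1:2] <- t(cross)
  if (p[["s1"]] != 0 || p[["s2"]] != 0)
    S <- interaction_transform(S, c(p[["s1"]], p[["s2"]]),
                               list(c(1L, 2L), c(3L, 4L)))
  S
}

full_path_vector <- function(par_named) {
  p <- c(a1 = 0, ab = 0, au = 0, c1 = 0, cb = 0, cu = 0,
         e1 = 0, eb = 0, eu = 0, s1 = 0, s2 = 0)
  p[names(par_named)] <- par_named
  p
}

#' Fit a bivariate longitudinal Cholesky twin model
#'
#' Maximizes the full-information Gaussian likelihood of the 4-vector
#' (twin1-t1, twin2-t1, twin1-t2, twin2-t2) under the two-timepoint
#' Cholesky decomposition with implied covariance
#' [implied_covariance_4x4()], one grand mean per timepoint, and
#' optional within-timepoint sibling-interaction coefficients `s1`,
#' `s2`. Nested families drop whole component rows (e.g. `"AE"` drops
#' `c1`, `cb`, `cu`). Pairs missing any subset of the four cells
#' contribute the marginal likelihood of their observed cells.
#'
#' Standardized output: timepoint-1 components \eqn{x_1^2 / V_1}; at
#' timepoint 2 the shared (carried-over) component of source X is
#' \eqn{x_b^2 / V_2} and the age-unique component \eqn{x_u^2 / V_2},
#' with \eqn{V_2} the pre-interaction timepoint-2 total, so shared plus
#' unique components sum to 1.
#'
#' @inheritParams fit_variance_components
#' @param ci compute Wald (delta-method) confidence intervals for the
#'   standardized components from the numerical Hessian. Default
#'   `FALSE`.
#' @param level confidence level for `ci`.
#' @return A `cholesky_fit` with path estimates, standardized t1 /
#'   shared / unique components, `minus2LL`, `aic`, and convergence
#'   flag.
#' @export
fit_cholesky <- function(cohort, phenotype,
                         model = c("ACE", "AE", "CE", "E"),
                         with_s = FALSE, n_starts = 8,
                         ci = FALSE, level = 0.95) {
  model <- match.arg(model)
  tps <- cohort_timepoints(cohort)
  if (length(tps) < 2)
    stop("a bivariate fit needs two timepoints")
  cols <- paste0(phenotype, "_", tps[1:2])
  if (!all(cols %in% names(cohort))) {
    # allow fully qualified first column + second guessed
    stop("phenotype columns ", paste(cols, collapse = ", "), " not found")
  }
  pm <- pair_matrix(cohort, cols)
  st <- list(MZ = fiml_stats(pm$MZ), DZ = fiml_stats(pm$DZ))
  for (z in c("MZ", "DZ"))
    if (st[[z]]$n_rows < 2)
      stop("insufficient data: need at least 2 pairs per zygosity")
  nm <- chol_param_names(model, with_s)

  obj <- function(par) {
    mu <- c(par[1], par[1], par[2], par[2])
    pv <- full_path_vector(stats::setNames(par[-(1:2)], nm))
    if (abs(pv[["s1"]]) >= 0.99 || abs(pv[["s2"]]) >= 0.99) return(Inf)
    m2 <- 0
    for (z in c("MZ", "DZ")) {
      Sg <- chol_sigma(pv, if (z == "MZ") 1 else 0.5)
      m2 <- m2 + fiml_neg2ll(st[[z]], mu, Sg)
    }
    m2
  }

  starts <- cholesky_starts(st, model, with_s, n_starts)
  res <- multi_start_optim(starts, obj)
  par <- res$par
  pv <- full_path_vector(stats::setNames(par[-(1:2)], nm))
  pv[setdiff(names(pv), c("s1", "s2"))] <-
    abs(pv[setdiff(names(pv), c("s1", "s2"))])
  V1 <- pv[["a1"]]^2 + pv[["c1"]]^2 + pv[["e1"]]^2
  V2 <- pv[["ab"]]^2 + pv[["au"]]^2 + pv[["cb"]]^2 + pv[["cu"]]^2 +
    pv[["eb"]]^2 + pv[["eu"]]^2
  std_t1 <- c(A = pv[["a1"]]^2, C = pv[["c1"]]^2, E = pv[["e1"]]^2) / V1
  shared <- c(A = pv[["ab"]]^2, C = pv[["cb"]]^2, E = pv[["eb"]]^2) / V2
  unique_ <- c(A = pv[["au"]]^2, C = pv[["cu"]]^2, E = pv[["eu"]]^2) / V2
  k_free <- 2L + length(nm)
  fit <- structure(list(
    model = model_label(model, with_s),
    family = model, with_s = with_s,
    params = pv,
    means = c(t1 = par[1], t2 = par[2]),
    std_t1 = std_t1, std_t2_shared = shared, std_t2_unique = unique_,
    s1 = if (with_s) pv[["s1"]] else NA_real_,
    s2 = if (with_s) pv[["s2"]] else NA_real_,
    minus2LL = res$value, k_free = k_free,
    aic = res$value + 2 * k_free,
    converged = res$converged,
    n_pairs = c(MZ = st$MZ$n_rows, DZ = st$DZ$n_rows),
    phenotype = paste(cols, collapse = "+"),
    stats = st, par_names = nm), class = "cholesky_fit")
  if (ci) attr(fit, "ci") <- cholesky_wald_ci(fit, obj, par, level)
  fit
}

# Method-of-moments starting values from complete-pattern moments.
cholesky_starts <- function(st, model, with_s, n_starts) {
  mom <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    for (pat in st[[z]]$patterns)
      if (length(pat$cols) == 4L)
        return(list(m = pat$mean, C = pat$scatter / pat$n))
    NULL
  })
  if (is.null(mom$MZ) || is.null(mom$DZ)) {
    mom <- list(MZ = list(m = rep(0, 4), C = diag(4) + 0.4 - 0.4 * diag(4)),
                DZ = list(m = rep(0, 4), C = diag(4) + 0.2 - 0.2 * diag(4)))
  }
  v1 <- mean(c(mom$MZ$C[1, 1], mom$MZ$C[2, 2], mom$DZ$C[1, 1],
               mom$DZ$C[2, 2]))
  v2 <- mean(c(mom$MZ$C[3, 3], mom$MZ$C[4, 4], mom$DZ$C[3, 3],
               mom$DZ$C[4, 4]))
  mu <- c(mean(c(mom$MZ$m[1:2], mom$DZ$m[1:2])),
          mean(c(mom$MZ$m[3:4], mom$DZ$m[3:4])))
  r1m <- mom$MZ$C[1, 2] / v1; r1d <- mom$DZ$C[1, 2] / v1
  r2m <- mom$MZ$C[3, 4] / v2; r2d <- mom$DZ$C[3, 4] / v2
  cph <- mean(c(mom$MZ$C[1, 3], mom$MZ$C[2, 4],
                mom$DZ$C[1, 3], mom$DZ$C[2, 4]))
  cxm <- mean(c(mom$MZ$C[1, 4], mom$MZ$C[2, 3]))
  cxd <- mean(c(mom$DZ$C[1, 4], mom$DZ$C[2, 3]))
  clip <- function(x, lo = 0.02, hi = 0.96) pmin(pmax(x, lo), hi)
  f1 <- clip(falconer_estimates(clip(r1m, -0.98, 0.98),
                                clip(r1d, -0.98, 0.98)))
  f2 <- clip(falconer_estimates(clip(r2m, -0.98, 0.98),
                                clip(r2d, -0.98, 0.98)))
  # cross-age covariance split by the same MZ/DZ contrast
  ca <- 2 * (cxm - cxd); cc <- 2 * cxd - cxm; ce <- cph - cxm
  mk <- function(carry_frac) {
    x1 <- sqrt(f1 * v1)
    totals2 <- f2 * v2
    xb <- c(A = ca, C = cc, E = ce) / pmax(x1, 0.05)
    xb <- sign(xb) * pmin(abs(xb), sqrt(carry_frac * totals2))
    xu <- sqrt(pmax(totals2 - xb^2, 0.01 * v2))
    full <- c(a1 = x1[["A"]], ab = xb[["A"]], au = xu[["A"]],
              c1 = x1[["C"]], cb = xb[["C"]], cu = xu[["C"]],
              e1 = x1[["E"]], eb = xb[["E"]], eu = xu[["E"]],
              s1 = 0, s2 = 0)
    nm <- chol_param_names(model, with_s)
    c(mu, full[nm])
  }
  starts <- list(mk(0.9), mk(0.25), mk(0.6))
  extra <- c(0.05, 0.45, 0.75, 0.95, 0.15)
  for (fr in extra[seq_len(max(0, n_starts - 3))])
    starts <- c(starts, list(mk(fr)))
  starts
}

cholesky_wald_ci <- function(fit, obj, par, level) {
  H <- numeric_hessian(obj, par)
  V <- tryCatch(solve(H / 2), error = function(e) NULL)  # -2LL Hessian
  if (is.null(V)) return(NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  qty <- function(p) {
    pv <- full_path_vector(stats::setNames(p[-(1:2)], fit$par_names))
    V1 <- pv[["a1"]]^2 + pv[["c1"]]^2 + pv[["e1"]]^2
    V2 <- pv[["ab"]]^2 + pv[["au"]]^2 + pv[["cb"]]^2 + pv[["cu"]]^2 +
      pv[["eb"]]^2 + pv[["eu"]]^2
    c(A_t1 = pv[["a1"]]^2 / V1, C_t1 = pv[["c1"]]^2 / V1,
      E_t1 = pv[["e1"]]^2 / V1,
      shared_A = pv[["ab"]]^2 / V2, shared_C = pv[["cb"]]^2 / V2,
      shared_E = pv[["eb"]]^2 / V2,
      unique_A = pv[["au"]]^2 / V2, unique_C = pv[["cu"]]^2 / V2,
      unique_E = pv[["eu"]]^2 / V2)
  }
  q0 <- qty(par)
  J <- vapply(seq_along(par), function(i) {
    h <- 1e-5
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (qty(pp) - qty(pm)) / (2 * h)
  }, numeric(length(q0)))
  se <- sqrt(pmax(0, diag(J %*% V %*% t(J))))
  cbind(lower = pmax(0, q0 - z * se), upper = pmin(1, q0 + z * se))
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("%s bivariate Cholesky model on %s (%d MZ / %d DZ pairs)\n",
              x$model, x$phenotype, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat(sprintf("  t1:      A = %.3f, C = %.3f, E = %.3f\n",
              x$std_t1["A"], x$std_t1["C"], x$std_t1["E"]))
  cat(sprintf("  t2 shared: A = %.3f, C = %.3f, E = %.3f\n",
              x$std_t2_shared["A"], x$std_t2_shared["C"],
              x$std_t2_shared["E"]))
  cat(sprintf("  t2 unique: A = %.3f, C = %.3f, E = %.3f\n",
              x$std_t2_unique["A"], x$std_t2_unique["C"],
              x$std_t2_unique["E"]))
  if (x$with_s)
    cat(sprintf("  interaction: s1 = %.3f, s2 = %.3f\n", x$s1, x$s2))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f (k = %d)%s\n",
              x$minus2LL, x$aic, x$k_free,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' Proportion of each later-age component shared with the earlier age
#'
#' For each source X in {A, C, E}, the share of its timepoint-2
#' variance that is carried over from timepoint 1:
#' \eqn{x_b^2 / (x_b^2 + x_u^2)}; the complement is the age-unique
#' share. Accepts either a fitted `cholesky_fit` or a named numeric
#' vector of standardized shared/unique components
#' (`shared_A`, `unique_A`, ...), e.g. transcribed from a published
#' table. A component with zero total variance has an undefined share,
#' returned as `NA`.
#'
#' @param fit a `cholesky_fit` or named numeric vector.
#' @return Data frame with columns `component`, `shared`, `unique`
#'   (proportions) and `shared_pct` (rounded to whole percent).
#' @examples
#' shared_variance_proportions(c(shared_C = 0.42, unique_C = 0.33))
#' @export
shared_variance_proportions <- function(fit) {
  if (inherits(fit, "cholesky_fit")) {
    sh <- fit$std_t2_shared; un <- fit$std_t2_unique
    comps <- c("A", "C", "E")
  } else {
    v <- fit
    comps <- intersect(c("A", "C", "E"),
                       sub("^(shared|unique)_", "",
                           names(v)[grepl("^shared_|^unique_", names(v))]))
    sh <- stats::setNames(v[paste0("shared_", comps)], comps)
    un <- stats::setNames(v[paste0("unique_", comps)], comps)
  }
  tot <- sh[comps] + un[comps]
  shared <- ifelse(tot > 0, sh[comps] / tot, NA_real_)
  data.frame(component = comps,
             shared = unname(shared),
             unique = unname(1 - shared),
             shared_pct = unname(round(100 * shared)),
             stringsAsFactors = FALSE)
}

#' Phenotypic and cross-twin cross-trait correlations across ages
#'
#' ML estimates from a constrained saturated 4-variate model with means
#' and variances equal across twin order: per-timepoint within-pair
#' correlations per zygosity, a phenotypic cross-age correlation shared
#' across zygosity (the conventional single reported value), and
#' per-zygosity cross-twin cross-trait correlations (twin 1 at one age
#' with twin 2 at the other). Wald CIs from the numerical Hessian on
#' the atanh scale.
#'
#' @inheritParams fit_cholesky
#' @param level confidence level, default 0.95.
#' @return A `cross_correlations` data frame: one row per correlation,
#'   with `estimate`, `lower`, `upper`.
#' @export
cross_correlations <- function(cohort, phenotype, level = 0.95) {
  tps <- cohort_timepoints(cohort)
  cols <- paste0(phenotype, "_", tps[1:2])
  pm <- pair_matrix(cohort, cols)
  st <- list(MZ = fiml_stats(pm$MZ), DZ = fiml_stats(pm$DZ))
  # par: mu1, mu2, logv1, logv2, zph, zr1_mz, zr2_mz, zcc_mz,
  #      zr1_dz, zr2_dz, zcc_dz
  build <- function(par, z) {
    v1 <- exp(par[3]); v2 <- exp(par[4])
    rph <- tanh(par[5])
    o <- if (z == "MZ") 0 else 3
    r1 <- tanh(par[6 + o]); r2 <- tanh(par[7 + o]); rcc <- tanh(par[8 + o])
    S <- matrix(0, 4, 4)
    S[1, 1] <- S[2, 2] <- v1
    S[3, 3] <- S[4, 4] <- v2
    S[1, 2] <- S[2, 1] <- v1 * r1
    S[3, 4] <- S[4, 3] <- v2 * r2
    sv <- sqrt(v1 * v2)
    S[1, 3] <- S[3, 1] <- S[2, 4] <- S[4, 2] <- sv * rph
    S[1, 4] <- S[4, 1] <- S[2, 3] <- S[3, 2] <- sv * rcc
    list(mu = c(par[1], par[1], par[2], par[2]), S = S)
  }
  obj <- function(par) {
    m2 <- 0
    for (z in c("MZ", "DZ")) {
      bz <- build(par, z)
      m2 <- m2 + fiml_neg2ll(st[[z]], bz$mu, bz$S)
    }
    m2
  }
  start <- c(0, 0, 0, 0, atanh(0.3), atanh(0.5), atanh(0.5), atanh(0.2),
             atanh(0.3), atanh(0.3), atanh(0.1))
  res <- multi_start_optim(list(start, start * 0.5), obj)
  H <- numeric_hessian(obj, res$par)
  V <- tryCatch(solve(H / 2), error = function(e) matrix(NA, 11, 11))
  se_z <- sqrt(pmax(diag(V), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  row <- function(label, i) data.frame(
    correlation = label, estimate = tanh(res$par[i]),
    lower = tanh(res$par[i] - zq * se_z[i]),
    upper = tanh(res$par[i] + zq * se_z[i]),
    stringsAsFactors = FALSE)
  out <- rbind(row("phenotypic cross-age", 5),
               row("within-pair t1 MZ", 6), row("within-pair t2 MZ", 7),
               row("cross-twin cross-trait MZ", 8),
               row("within-pair t1 DZ", 9), row("within-pair t2 DZ", 10),
               row("cross-twin cross-trait DZ", 11))
  class(out) <- c("cross_correlations", "data.frame")
  out
}
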