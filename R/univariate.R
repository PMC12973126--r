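# Univariate twin models: saturated baseline, ACE/AE/CE/E variants with
# optional sibling interaction, model comparison and selection, profile
# likelihood confidence intervals.

resolve_column <- function(cohort, phenotype, timepoint) {
  if (phenotype %in% names(cohort)) return(phenotype)
  col <- paste0(phenotype, "_", timepoint)
  if (!col %in% names(cohort))
    stop("phenotype column '", col, "' not found")
  col
}

univariate_stats <- function(cohort, phenotype, timepoint = "t1") {
  col <- resolve_column(cohort, phenotype, timepoint)
  pm <- pair_matrix(cohort, col)
  list(MZ = fiml_stats(pm$MZ), DZ = fiml_stats(pm$DZ), column = col)
}

# Complete-pair moments (ML denominators) used for starting values.
pair_moment_summary <- function(st) {
  out <- list(mean = 0, v = 1, r = c(MZ = 0.5, DZ = 0.25))
  vs <- c(); ms <- c()
  for (z in c("MZ", "DZ")) {
    for (pat in st[[z]]$patterns) {
      if (length(pat$cols) == 2L) {
        C <- pat$scatter / pat$n
        out$r[z] <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
        vs <- c(vs, diag(C) * pat$n)
        ms <- c(ms, pat$mean * pat$n)
      }
    }
  }
  if (length(vs)) {
    tot_n <- sum(vapply(c(st$MZ$patterns, st$DZ$patterns),
                        function(p) if (length(p$cols) == 2L) p$n else 0L,
                        numeric(1)))
    out$v <- sum(vs) / (2 * tot_n)
    out$mean <- sum(ms) / (2 * tot_n)
  }
  out
}

# Closed-form ACE-s pair covariance (avoids constructor overhead in the
# optimizer inner loop).
acs_sigma <- function(a, c, e, s, rho) {
  u <- a^2 + c^2 + e^2
  w <- rho * a^2 + c^2
  if (s != 0) {
    f <- 1 / (1 - s^2)^2
    du <- f * (u * (1 + s^2) + 2 * s * w)
    dw <- f * (w * (1 + s^2) + 2 * s * u)
    u <- du; w <- dw
  }
  matrix(c(u, w, w, u), 2, 2)
}

model_paths <- function(model) {
  switch(model, ACE = c("a", "c", "e"), AE = c("a", "e"),
         CE = c("c", "e"), E = "e",
         stop("unknown model family '", model, "'"))
}

model_label <- function(model, with_s) paste0(model, if (with_s) "-s")

parse_label <- function(label) {
  with_s <- grepl("-s$", label)
  list(model = sub("-s$", "", label), with_s = with_s)
}

#' Fit a univariate twin variance-components model
#'
#' Maximizes the full-information Gaussian likelihood of twin-pair data
#' under the ACE model or one of its nested reductions (AE, CE, E), with
#' an optional sibling-interaction coefficient `s`. The implied pair
#' covariance is [pair_covariance()] per zygosity with a single grand
#' mean (means are assumption-tested and covariate-residualized
#' upstream). Paths enter unconstrained and are squared into variances,
#' so the implied covariance is positive semi-definite by construction
#' and path signs are reported as magnitudes. Incomplete pairs
#' contribute the marginal likelihood of the observed twin.
#'
#' Standardized components are the squared paths divided by the
#' pre-interaction total \eqn{a^2 + c^2 + e^2}; when `with_s` the
#' interaction coefficient is reported separately (the components still
#' sum to 1).
#'
#' @param cohort a [twin_cohort()].
#' @param phenotype phenotype column name (or base name combined with
#'   `timepoint`).
#' @param model one of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param with_s include the sibling-interaction coefficient.
#' @param timepoint timepoint label, default `"t1"`.
#' @param n_starts number of jittered starting points around the
#'   method-of-moments (Falconer) start, default 10.
#' @param extra_starts optional list of additional full parameter
#'   vectors (mean, paths, s) to try.
#' @return A `twin_fit` object: path estimates, standardized components,
#'   `minus2LL`, `aic`, free-parameter count, convergence flag.
#' @examples
#' coh <- make_exact_correlation_cohort(0.91, 0.76, seed = 1)
#' fit <- fit_variance_components(coh, "y_t1", model = "ACE")
#' fit$std  # A, C, E close to 0.30, 0.61, 0.09
#' @export
fit_variance_components <- function(cohort, phenotype,
                                    model = c("ACE", "AE", "CE", "E"),
                                    with_s = FALSE, timepoint = "t1",
                                    n_starts = 10, extra_starts = NULL) {
  model <- match.arg(model)
  st <- univariate_stats(cohort, phenotype, timepoint)
  check_min_pairs(st)
  paths <- model_paths(model)
  mom <- pair_moment_summary(st)

  obj <- function(par) {
    mu <- par[1]
    p <- c(a = 0, c = 0, e = 0, s = 0)
    p[paths] <- par[2:(1 + length(paths))]
    if (with_s) {
      p["s"] <- par[length(par)]
      if (abs(p["s"]) >= 0.99) return(Inf)
    }
    m2 <- 0
    for (z in c("MZ", "DZ")) {
      Sg <- acs_sigma(p[["a"]], p[["c"]], p[["e"]], p[["s"]],
                      if (z == "MZ") 1 else 0.5)
      m2 <- m2 + fiml_neg2ll(st[[z]], c(mu, mu), Sg)
    }
    m2
  }

  fal <- falconer_estimates(mom$r["MZ"], mom$r["DZ"])
  clip <- function(x) pmin(pmax(x, 0.02), 0.96)
  base <- c(A = clip(fal[["A"]]), C = clip(fal[["C"]]), E = clip(fal[["E"]]))
  mk_start <- function(w) {
    w <- w / sum(w)
    out <- c(mom$mean, sqrt(w[paths_to_comp(paths)] * mom$v))
    if (with_s) out <- c(out, 0)
    out
  }
  paths_to_comp <- function(p) c(a = "A", c = "C", e = "E")[p]
  starts <- list(mk_start(base), mk_start(c(A = 1, C = 1, E = 1)))
  jitter_grid <- c(0.5, 2, 0.25, 4, 0.75, 1.5, 8, 0.1)
  for (j in jitter_grid[seq_len(max(0, n_starts - 2))]) {
    w <- base; w["E"] <- w["E"] * j
    starts <- c(starts, list(mk_start(w)))
  }
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)

  res <- multi_start_optim(starts, obj)
  par <- res$par
  p <- c(a = 0, c = 0, e = 0, s = 0)
  p[paths] <- abs(par[2:(1 + length(paths))])
  if (with_s) p["s"] <- par[length(par)]
  tot <- p[["a"]]^2 + p[["c"]]^2 + p[["e"]]^2
  std <- c(A = p[["a"]]^2, C = p[["c"]]^2, E = p[["e"]]^2) / tot
  k_free <- 1L + length(paths) + as.integer(with_s)
  n_pairs <- c(MZ = st$MZ$n_rows, DZ = st$DZ$n_rows)
  structure(list(
    model = model_label(model, with_s),
    family = model, with_s = with_s,
    paths = p[c("a", "c", "e")], s = if (with_s) p[["s"]] else NA_real_,
    mean = par[1],
    std = std,
    minus2LL = res$value,
    k_free = k_free,
    aic = res$value + 2 * k_free,
    converged = res$converged,
    n_pairs = n_pairs,
    phenotype = st$column,
    stats = st), class = "twin_fit")
}

check_min_pairs <- function(st) {
  for (z in c("MZ", "DZ"))
    if (st[[z]]$n_rows < 2)
      stop("insufficient data: need at least 2 pairs per zygosity")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s twin model on %s (%d MZ / %d DZ pairs)\n",
              x$model, x$phenotype, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat(sprintf("  A = %.3f, C = %.3f, E = %.3f%s\n",
              x$std["A"], x$std["C"], x$std["E"],
              if (!is.na(x$s)) sprintf(", s = %.3f", x$s) else ""))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f (k = %d)%s\n",
              x$minus2LL, x$aic, x$k_free,
              if (!x$converged) "  [not converged]" else ""))
  ci <- attr(x, "ci")
  if (!is.null(ci)) {
    for (i in seq_len(nrow(ci)))
      cat(sprintf("  %s: [%.3f; %.3f]\n", rownames(ci)[i],
                  ci[i, 1], ci[i, 2]))
  }
  invisible(x)
}

#' Method-of-moments (Falconer) estimates from twin correlations
#'
#' `A = 2 (rMZ - rDZ)`, `C = 2 rDZ - rMZ`, `E = 1 - rMZ`. Raw values
#' are returned without truncation, so they can fall outside [0, 1]
#' when the correlations do not conform to the ACE structure.
#'
#' @param r_mz,r_dz within-pair correlations, each in [-1, 1].
#' @return Named numeric vector `c(A, C, E)`.
#' @examples
#' falconer_estimates(0.91, 0.76)  # A 0.30, C 0.61, E 0.09
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  r_mz <- unname(r_mz); r_dz <- unname(r_dz)
  c(A = 2 * (r_mz - r_dz), C = 2 * r_dz - r_mz, E = 1 - r_mz)
}

#' Twin correlations implied by a fitted (or stated) twin model
#'
#' With no sibling interaction the implied correlations on the
#' standardized scale are `rMZ = A + C` and `rDZ = A/2 + C`. With
#' interaction they are computed from the full interaction-adjusted
#' pair covariance.
#'
#' @param fit a `twin_fit`, an [ace_params()], or a named numeric
#'   vector with elements `A` and `C` (standardized components, e.g.
#'   taken from a published table).
#' @return Named numeric vector `c(r_mz, r_dz)`.
#' @examples
#' implied_twin_correlations(c(A = 0.56, C = 0.26))  # 0.82, 0.54
#' @export
implied_twin_correlations <- function(fit) {
  if (inherits(fit, "twin_fit")) {
    s <- if (is.na(fit$s)) 0 else fit$s
    prm <- ace_params(fit$paths[["a"]], fit$paths[["c"]], fit$paths[["e"]],
                      s = s)
  } else if (inherits(fit, "ace_params")) {
    prm <- fit
  } else {
    A <- fit[["A"]]; C <- fit[["C"]]
    E <- if ("E" %in% names(fit)) fit[["E"]] else 1 - A - C
    return(c(r_mz = A + C, r_dz = 0.5 * A + C))
  }
  if (prm$s == 0) {
    tot <- prm$a^2 + prm$c^2 + prm$e^2
    return(c(r_mz = (prm$a^2 + prm$c^2) / tot,
             r_dz = (0.5 * prm$a^2 + prm$c^2) / tot))
  }
  r <- vapply(c("MZ", "DZ"), function(z) {
    S <- pair_covariance(prm, z)
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  }, numeric(1))
  c(r_mz = r[["MZ"]], r_dz = r[["DZ"]])
}

is_nested_label <- function(restricted, general) {
  r <- parse_label(restricted); g <- parse_label(general)
  letters_r <- strsplit(r$model, "")[[1]]
  letters_g <- strsplit(g$model, "")[[1]]
  all(letters_r %in% letters_g) && (!r$with_s || g$with_s)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' The difference in -2 log likelihood between a restricted model and a
#' more general model it is nested in, referred to a chi-squared
#' distribution with the difference in free parameters as degrees of
#' freedom. The difference is floored at zero (with exact arithmetic a
#' nested optimum can never beat the general one).
#'
#' @param restricted,general `twin_fit` (or `cholesky_fit`) objects
#'   fitted to the same data.
#' @return A `model_comparison` object with `delta_chi2`, `delta_df`,
#'   and `p`.
#' @export
compare_models <- function(restricted, general) {
  if (!is_nested_label(restricted$model, general$model))
    stop("'", restricted$model, "' is not nested in '", general$model, "'")
  if (!identical(restricted$phenotype, general$phenotype) ||
      !identical(restricted$n_pairs, general$n_pairs))
    stop("model comparison requires fits to the same data")
  delta_df <- general$k_free - restricted$k_free
  delta <- max(0, restricted$minus2LL - general$minus2LL)
  p <- if (delta_df <= 0) 1 else
    stats::pchisq(delta, delta_df, lower.tail = FALSE)
  structure(list(delta_chi2 = delta, delta_df = delta_df, p = p,
                 restricted = restricted$model, general = general$model),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: delta chi2 = %.4g (df %d), p = %.3g\n",
              x$restricted, x$general, x$delta_chi2, x$delta_df, x$p))
  invisible(x)
}

#' Select the best-fitting parsimonious twin model
#'
#' Among candidate fits whose likelihood-ratio test against the
#' reference (most general) model is non-significant — i.e. whose fit is
#' not measurably worse — returns the one minimizing AIC. Ties within
#' `1e-9` go to the model with fewer free parameters, then to a fixed
#' family order (E, CE, AE, ACE, then the `-s` variants), so selection
#' is deterministic. If every candidate fits significantly worse than
#' the reference, the reference itself is returned with a warning.
#'
#' @param fits list of `twin_fit` objects on the same data.
#' @param reference the general model to test decrement-in-fit against
#'   (typically the ACE-s fit, or a saturated fit's `minus2LL` wrapped
#'   in a fit object).
#' @param alpha LRT significance level for "no decrement in fit",
#'   default 0.05.
#' @return The selected fit, with the per-candidate comparison table in
#'   `attr(, "selection")`.
#' @export
select_model <- function(fits, reference, alpha = 0.05) {
  if (length(fits) == 0) stop("no candidate fits supplied")
  family_order <- c("E", "CE", "AE", "ACE", "E-s", "CE-s", "AE-s", "ACE-s")
  tab <- do.call(rbind, lapply(fits, function(f) {
    cmp <- compare_models(f, reference)
    data.frame(model = f$model, minus2LL = f$minus2LL, aic = f$aic,
               k_free = f$k_free, delta_chi2 = cmp$delta_chi2,
               delta_df = cmp$delta_df, p = cmp$p,
               stringsAsFactors = FALSE)
  }))
  ok <- which(tab$p >= alpha)
  if (length(ok) == 0) {
    warning("every candidate fits worse than the reference; returning it")
    sel <- reference
  } else {
    cand <- tab[ok, , drop = FALSE]
    best_aic <- min(cand$aic)
    tied <- cand[cand$aic - best_aic < 1e-9, , drop = FALSE]
    tied <- tied[order(tied$k_free, match(tied$model, family_order)), ,
                 drop = FALSE]
    sel <- fits[[which(vapply(fits, function(f) f$model, "") ==
                         tied$model[1])[1]]]
  }
  attr(sel, "selection") <- tab
  sel
}

#' Profile-likelihood confidence interval for a model component
#'
#' Likelihood-based interval for a standardized variance component (or
#' the interaction coefficient `s`): the set of values at which the
#' profile -2 log likelihood — re-maximized over all other parameters —
#' stays within the chi-squared(1) quantile (3.84 at 95%) of the
#' minimum. Standardized components are bounded to [0, 1]. If the fixed
#' component is structurally absent from the model family (e.g. C in an
#' AE model) the interval is degenerate at its fixed value.
#'
#' @param fit a `twin_fit`.
#' @param component `"A"`, `"C"`, `"E"`, or `"s"`.
#' @param level confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
profile_ci <- function(fit, component = c("A", "C", "E", "s"),
                       level = 0.95) {
  component <- match.arg(component)
  thr <- fit$minus2LL + stats::qchisq(level, 1)
  if (component == "s") {
    if (!fit$with_s) stop("fit has no interaction coefficient")
    prof <- function(sv) profiled_min(fit, s_fix = sv)
    return(profile_bounds(prof, fit$s, thr, lo_lim = -0.98, hi_lim = 0.98))
  }
  comp_letter <- c(A = "a", C = "c", E = "e")[component]
  active <- model_paths(fit$family)
  if (!comp_letter %in% active) {
    val <- fit$std[[component]]
    return(c(lower = val, upper = val))
  }
  if (length(active) == 1L)  # E-only: component pinned at 1
    return(c(lower = 1, upper = 1))
  prof <- function(p) profiled_min(fit, comp_fix = c(component, p))
  profile_bounds(prof, fit$std[[component]], thr, lo_lim = 0, hi_lim = 1)
}

# Minimized -2LL with one standardized component (or s) held fixed.
profiled_min <- function(fit, comp_fix = NULL, s_fix = NULL) {
  st <- fit$stats
  active <- model_paths(fit$family)
  with_s <- fit$with_s
  comps <- c(a = "A", c = "C", e = "E")[active]

  if (!is.null(s_fix)) {
    obj <- function(par) {
      mu <- par[1]
      p <- c(a = 0, c = 0, e = 0)
      p[active] <- par[-1]
      m2 <- 0
      for (z in c("MZ", "DZ")) {
        Sg <- acs_sigma(p[["a"]], p[["c"]], p[["e"]], s_fix,
                        if (z == "MZ") 1 else 0.5)
        m2 <- m2 + fiml_neg2ll(st[[z]], c(mu, mu), Sg)
      }
      m2
    }
    start <- c(fit$mean, pmax(fit$paths[active], 1e-3))
    return(multi_start_optim(list(start, start * 0.7 + 0.01), obj)$value)
  }

  comp <- comp_fix[1]
  pfix <- as.numeric(comp_fix[2])
  others <- setdiff(comps, comp)
  # free: mu, log total variance, (logit split among two others), (s)
  tot_hat <- sum(fit$paths^2)
  obj <- function(par) {
    mu <- par[1]
    logT <- par[2]
    TT <- exp(logT)
    if (length(others) == 2L) {
      q <- stats::plogis(par[3])
      w <- c(pfix, (1 - pfix) * q, (1 - pfix) * (1 - q))
      names(w) <- c(comp, others)
    } else {
      w <- c(pfix, 1 - pfix)
      names(w) <- c(comp, others)
    }
    sv <- if (with_s) par[length(par)] else 0
    if (abs(sv) >= 0.99) return(Inf)
    p <- c(a = 0, c = 0, e = 0)
    for (lv in names(w)) p[c(A = "a", C = "c", E = "e")[lv]] <- sqrt(w[lv] * TT)
    m2 <- 0
    for (z in c("MZ", "DZ")) {
      Sg <- acs_sigma(p[["a"]], p[["c"]], p[["e"]], sv,
                      if (z == "MZ") 1 else 0.5)
      m2 <- m2 + fiml_neg2ll(st[[z]], c(mu, mu), Sg)
    }
    m2
  }
  start <- c(fit$mean, log(tot_hat))
  if (length(others) == 2L) {
    oth_hat <- pmax(fit$std[others], 1e-4)
    start <- c(start, stats::qlogis(oth_hat[1] / sum(oth_hat)))
  }
  if (with_s) start <- c(start, if (is.na(fit$s)) 0 else fit$s)
  starts <- list(start, start + c(0, 0.2, rep(0, length(start) - 2)))
  multi_start_optim(starts, obj)$value
}

profile_bounds <- function(prof, hat, thr, lo_lim, hi_lim) {
  eps <- 1e-6
  hat <- min(max(hat, lo_lim + eps), hi_lim - eps)
  lower <- if (prof(lo_lim + eps) <= thr) lo_lim else
    stats::uniroot(function(p) prof(p) - thr, c(lo_lim + eps, hat),
                   tol = 1e-5)$root
  upper <- if (prof(hi_lim - eps) <= thr) hi_lim else
    stats::uniroot(function(p) prof(p) - thr, c(hat, hi_lim - eps),
                   tol = 1e-5)$root
  c(lower = lower, upper = upper)
}

# ---------------------------------------------------------------------
# Saturated model and assumption tests

sat2_objective <- function(st_z, mu, Sigma) fiml_neg2ll(st_z, mu, Sigma)

fit_sat2 <- function(st, constraint = c("none", "eq_means",
                                        "eq_means_vars", "eq_var_zyg",
                                        "eq_all")) {
  constraint <- match.arg(constraint)
  build <- function(par, z) {
    switch(constraint,
      none = {
        o <- if (z == "MZ") 0 else 5
        list(mu = par[o + 1:2],
             Sigma = cov_from(par[o + 3], par[o + 4], par[o + 5]))
      },
      eq_means = {
        o <- if (z == "MZ") 0 else 4
        list(mu = rep(par[o + 1], 2),
             Sigma = cov_from(par[o + 2], par[o + 3], par[o + 4]))
      },
      eq_means_vars = {
        o <- if (z == "MZ") 0 else 3
        list(mu = rep(par[o + 1], 2),
             Sigma = cov_from(par[o + 2], par[o + 2], par[o + 3]))
      },
      eq_var_zyg = list(
        mu = rep(if (z == "MZ") par[1] else par[2], 2),
        Sigma = cov_from(par[3], par[3],
                         if (z == "MZ") par[4] else par[5])),
      eq_all = list(mu = rep(par[1], 2),
                    Sigma = cov_from(par[2], par[2],
                                     if (z == "MZ") par[3] else par[4])))
  }
  cov_from <- function(lv1, lv2, zc) {
    v1 <- exp(lv1); v2 <- exp(lv2)
    cv <- sqrt(v1 * v2) * tanh(zc)
    matrix(c(v1, cv, cv, v2), 2, 2)
  }
  k <- switch(constraint, none = 10L, eq_means = 8L,
              eq_means_vars = 6L, eq_var_zyg = 5L, eq_all = 4L)
  obj <- function(par) {
    m2 <- 0
    for (z in c("MZ", "DZ")) {
      bz <- build(par, z)
      m2 <- m2 + fiml_neg2ll(st[[z]], bz$mu, bz$Sigma)
    }
    m2
  }
  mom <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    for (pat in st[[z]]$patterns)
      if (length(pat$cols) == 2L)
        return(list(m = pat$mean, C = pat$scatter / pat$n))
    list(m = c(0, 0), C = diag(2))
  })
  zc <- function(C) atanh(min(max(C[1, 2] / sqrt(C[1, 1] * C[2, 2]),
                                  -0.99), 0.99))
  start <- switch(constraint,
    none = c(mom$MZ$m, log(diag(mom$MZ$C)), zc(mom$MZ$C),
             mom$DZ$m, log(diag(mom$DZ$C)), zc(mom$DZ$C)),
    eq_means = c(mean(mom$MZ$m), log(diag(mom$MZ$C)), zc(mom$MZ$C),
                 mean(mom$DZ$m), log(diag(mom$DZ$C)), zc(mom$DZ$C)),
    eq_means_vars = c(mean(mom$MZ$m), log(mean(diag(mom$MZ$C))), zc(mom$MZ$C),
                      mean(mom$DZ$m), log(mean(diag(mom$DZ$C))), zc(mom$DZ$C)),
    eq_var_zyg = c(mean(mom$MZ$m), mean(mom$DZ$m),
                   log(mean(c(diag(mom$MZ$C), diag(mom$DZ$C)))),
                   zc(mom$MZ$C), zc(mom$DZ$C)),
    eq_all = c(mean(c(mom$MZ$m, mom$DZ$m)),
               log(mean(c(diag(mom$MZ$C), diag(mom$DZ$C)))),
               zc(mom$MZ$C), zc(mom$DZ$C)))
  res <- multi_start_optim(list(start, start * 0.9), obj)
  list(minus2LL = res$value, k_free = k, par = res$par,
       converged = res$converged, build = build)
}

#' Fit the fully saturated twin model and test modeling assumptions
#'
#' Unconstrained bivariate-normal fit per zygosity (means and variances
#' per twin order, within-pair covariance per zygosity), by full
#' information ML so incomplete pairs contribute their observed twin.
#' Nested constrained fits provide likelihood-ratio tests of the twin
#' modeling assumptions: equality of means across twin order, equality
#' of variances across twin order, and equality of means and variances
#' across zygosity (the last is the one sibling interaction violates —
#' under `s != 0` MZ and DZ total variances differ).
#'
#' @inheritParams fit_variance_components
#' @return A `saturated_fit` with per-zygosity moments, `minus2LL`
#'   (`k_free` = 10), and an `assumption_tests` data frame of LRTs.
#' @export
fit_saturated <- function(cohort, phenotype, timepoint = "t1") {
  st <- univariate_stats(cohort, phenotype, timepoint)
  check_min_pairs(st)
  full <- fit_sat2(st, "none")
  eqm <- fit_sat2(st, "eq_means")
  eqmv <- fit_sat2(st, "eq_means_vars")
  eqvz <- fit_sat2(st, "eq_var_zyg")
  eqall <- fit_sat2(st, "eq_all")
  lrt <- function(restr, gen, df, label) {
    d <- max(0, restr$minus2LL - gen$minus2LL)
    data.frame(test = label, delta_chi2 = d, delta_df = df,
               p = stats::pchisq(d, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  tests <- rbind(
    lrt(eqm, full, 2L, "equal means across twin order"),
    lrt(eqmv, eqm, 2L, "equal variances across twin order"),
    lrt(eqvz, eqmv, 1L, "equal variances across zygosity"),
    lrt(eqall, eqvz, 1L, "equal means across zygosity"))
  moments <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    bz <- full$build(full$par, z)
    list(mean = bz$mu, Sigma = bz$Sigma)
  })
  structure(list(minus2LL = full$minus2LL, k_free = 10L,
                 aic = full$minus2LL + 20,
                 model = "saturated",
                 moments = moments, assumption_tests = tests,
                 converged = full$converged,
                 n_pairs = c(MZ = st$MZ$n_rows, DZ = st$DZ$n_rows),
                 phenotype = st$column, stats = st),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("Saturated twin model on %s: -2LL = %.2f (k = 10)\n",
              x$phenotype, x$minus2LL))
  for (z in c("MZ", "DZ")) {
    S <- x$moments[[z]]$Sigma
    cat(sprintf("  %s: means (%.3f, %.3f), vars (%.3f, %.3f), r = %.3f\n",
                z, x$moments[[z]]$mean[1], x$moments[[z]]$mean[2],
                S[1, 1], S[2, 2], S[1, 2] / sqrt(S[1, 1] * S[2, 2])))
  }
  cat("Assumption tests:\n")
  print(x$assumption_tests, row.names = FALSE)
  invisible(x)
}

#' Maximum-likelihood twin correlations with profile CIs
#'
#' Within-pair correlation per zygosity from a saturated model
#' constrained to equal means and variances across twin order (the
#' standard twin-correlation model), with likelihood-profile confidence
#' intervals on the correlation.
#'
#' @inheritParams fit_variance_components
#' @param level confidence level, default 0.95.
#' @param ci compute profile intervals (set `FALSE` to skip).
#' @return Data frame with one row per zygosity: `r`, `lower`, `upper`,
#'   `n_pairs`.
#' @export
twin_correlations <- function(cohort, phenotype, timepoint = "t1",
                              level = 0.95, ci = TRUE) {
  st <- univariate_stats(cohort, phenotype, timepoint)
  check_min_pairs(st)
  out <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    stz <- st[[z]]
    obj <- function(par) {
      v <- exp(par[2]); cv <- v * tanh(par[3])
      fiml_neg2ll(stz, rep(par[1], 2),
                  matrix(c(v, cv, cv, v), 2, 2))
    }
    mom <- pair_moment_summary(list(MZ = stz, DZ = stz,
                                    column = st$column))
    start <- c(mom$mean, log(mom$v), atanh(min(max(mom$r[[z]], -0.98),
                                               0.98)))
    res <- multi_start_optim(list(start, start + c(0, 0.3, 0)), obj)
    r_hat <- tanh(res$par[3])
    lo <- hi <- NA_real_
    if (ci) {
      thr <- res$value + stats::qchisq(level, 1)
      prof <- function(r) {
        o2 <- function(par) {
          v <- exp(par[2]); cv <- v * r
          fiml_neg2ll(stz, rep(par[1], 2),
                      matrix(c(v, cv, cv, v), 2, 2))
        }
        multi_start_optim(list(res$par[1:2]), o2)$value
      }
      b <- profile_bounds(prof, r_hat, thr, lo_lim = -1, hi_lim = 1)
      lo <- b[["lower"]]; hi <- b[["upper"]]
    }
    data.frame(zygosity = z, r = r_hat, lower = lo, upper = hi,
               n_pairs = stz$n_rows, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
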