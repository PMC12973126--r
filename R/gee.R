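# Population-averaged Gaussian regression for twin-clustered data:
# generalized estimating equations with an exchangeable or independence
# working correlation and a cluster-robust (sandwich) covariance.

#' Generalized estimating equations for clustered Gaussian data
#'
#' Solves the Gaussian estimating equations
#' \eqn{\sum_i X_i^\top V_i^{-1} (y_i - X_i\beta) = 0} with working
#' covariance \eqn{V_i = \phi R(\alpha)} per cluster, where `R` is
#' exchangeable (within-cluster correlation \eqn{\alpha} estimated by
#' moment matching from the Pearson residuals) or the identity. The
#' reported covariance is always the cluster-robust sandwich
#' \eqn{B^{-1} M B^{-\top}} with \eqn{B = \sum_i X_i^\top V_i^{-1} X_i}
#' and \eqn{M = \sum_i X_i^\top V_i^{-1} r_i r_i^\top V_i^{-1} X_i}, so
#' inference is consistent whichever working structure is chosen. With
#' all clusters of size one and independence working structure the
#' coefficients equal ordinary least squares and the sandwich reduces
#' to the heteroskedasticity-robust (HC0) form.
#'
#' @param y numeric response vector.
#' @param X design matrix (with intercept column if wanted); must have
#'   full column rank.
#' @param cluster_ids cluster (twin-pair) identifier per row.
#' @param working_structure `"exchangeable"` (default, the natural
#'   choice for twins) or `"independence"`.
#' @param small_sample apply an HC1-style cluster-count correction
#'   `G/(G-1) * (N-1)/(N-p)` to the sandwich. Default `FALSE` (the
#'   study regime has hundreds of clusters).
#' @param max_iter,tol iteration control for the alternating beta /
#'   alpha updates.
#' @return A `gee_fit`: `coefficients`, `robust_covariance`, `z`, `p`,
#'   `n_clusters`, `alpha`, `phi`, `working_structure`.
#' @export
fit_gee <- function(y, X, cluster_ids,
                    working_structure = c("exchangeable", "independence"),
                    small_sample = FALSE, max_iter = 50, tol = 1e-10) {
  working_structure <- match.arg(working_structure)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  cluster_ids <- cluster_ids[keep]
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design: X is rank deficient")
  cl <- split(seq_len(n), as.character(cluster_ids))
  G <- length(cl)
  if (G < 2) stop("degenerate variance: need at least 2 clusters")

  beta <- qr.solve(X, y)
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (working_structure == "exchangeable") {
      num <- 0; npairs <- 0
      for (idx in cl) {
        if (length(idx) < 2) next
        ri <- r[idx]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        npairs <- npairs + choose(length(idx), 2)
      }
      alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
      alpha <- min(max(alpha, -0.99), 0.99)
    }
    B <- matrix(0, p, p); u <- numeric(p)
    for (idx in cl) {
      m <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      Rinv <- if (working_structure == "independence" || m == 1) diag(m)
      else solve((1 - alpha) * diag(m) + alpha * matrix(1, m, m))
      W <- Rinv / phi
      B <- B + crossprod(Xi, W %*% Xi)
      u <- u + crossprod(Xi, W %*% y[idx])
    }
    beta_new <- drop(solve(B, u))
    if (sum((beta_new - beta)^2) < tol * (1 + sum(beta^2))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  r <- y - drop(X %*% beta)
  phi <- sum(r^2) / (n - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in cl) {
    m <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    Rinv <- if (working_structure == "independence" || m == 1) diag(m)
    else solve((1 - alpha) * diag(m) + alpha * matrix(1, m, m))
    W <- Rinv / phi
    B <- B + crossprod(Xi, W %*% Xi)
    si <- crossprod(Xi, W %*% r[idx])
    M <- M + si %*% t(si)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% t(Binv)
  if (small_sample) V <- V * G / (G - 1) * (n - 1) / (n - p)
  V <- (V + t(V)) / 2
  se <- sqrt(diag(V))
  z <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 robust_covariance = V,
                 se = stats::setNames(se, colnames(X)),
                 z = stats::setNames(z, colnames(X)),
                 p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
                 n = n, n_clusters = G, alpha = alpha, phi = phi,
                 working_structure = working_structure),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s working correlation, %d obs in %d clusters)\n",
              x$working_structure, x$n, x$n_clusters))
  tab <- data.frame(estimate = x$coefficients, robust_se = x$se,
                    z = x$z, p = x$p)
  print(round(tab, 4))
  if (x$working_structure == "exchangeable")
    cat(sprintf("working alpha = %.3f, dispersion = %.3f\n",
                x$alpha, x$phi))
  invisible(x)
}

# Build a design matrix from cohort columns (numeric as-is, factors /
# characters expanded to treatment contrasts), with an intercept.
design_matrix <- function(cohort, vars) {
  df <- as.data.frame(cohort)[, vars, drop = FALSE]
  for (v in vars)
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  stats::model.matrix(~ ., data = df)
}

#' Screen background covariates for association with a phenotype
#'
#' One population-averaged regression of the phenotype on each
#' background variable in turn (clustered on twin pair), flagging
#' variables whose cluster-robust Wald p-value falls below `alpha`:
#' those are the variables to regress out of the phenotype before the
#' twin analyses. Constant covariates are skipped with a warning.
#'
#' @param cohort a [twin_cohort()].
#' @param phenotype phenotype column name.
#' @param background_vars character vector of covariate column names.
#' @param alpha flagging threshold, default 0.05.
#' @param working_structure passed to [fit_gee()].
#' @return Data frame: `variable`, `beta`, `robust_se`, `z`, `p`,
#'   `flagged`.
#' @export
screen_covariates <- function(cohort, phenotype, background_vars,
                              alpha = 0.05,
                              working_structure = "exchangeable") {
  stopifnot(phenotype %in% names(cohort))
  rows <- lapply(background_vars, function(v) {
    if (!v %in% names(cohort)) stop("covariate '", v, "' not found")
    x <- cohort[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate '", v, "' is constant; skipped")
      return(NULL)
    }
    X <- design_matrix(cohort, v)
    fit <- fit_gee(cohort[[phenotype]], X, cohort$pair_id,
                   working_structure = working_structure)
    j <- 2L  # first non-intercept column
    data.frame(variable = v, beta = fit$coefficients[j],
               robust_se = fit$se[j], z = fit$z[j], p = fit$p[j],
               flagged = fit$p[j] < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress covariates out of a phenotype (population-averaged)
#'
#' Residualizes a phenotype on the given covariates using the
#' population-averaged (GEE) fitted mean — sex and assessment age are
#' always included by the screening pipeline, with flagged background
#' variables appended. Rows with missing covariate cells get a missing
#' residual. The residualized column `<phenotype>_resid` is appended to
#' the cohort.
#'
#' @param cohort a [twin_cohort()].
#' @param phenotype phenotype column name.
#' @param covariates character vector of covariate column names; if
#'   empty the residual is the centered phenotype.
#' @param working_structure passed to [fit_gee()].
#' @return The cohort with `<phenotype>_resid` appended.
#' @export
residualize <- function(cohort, phenotype, covariates = character(0),
                        working_structure = "exchangeable") {
  stopifnot(phenotype %in% names(cohort))
  y <- cohort[[phenotype]]
  out <- as.data.frame(cohort)
  if (length(covariates) == 0) {
    out[[paste0(phenotype, "_resid")]] <- y - mean(y, na.rm = TRUE)
  } else {
    X <- design_matrix(cohort, covariates)
    keep <- stats::complete.cases(y, X)
    fit <- fit_gee(y, X, cohort$pair_id,
                   working_structure = working_structure)
    resid <- rep(NA_real_, length(y))
    resid[keep] <- y[keep] -
      drop(X[keep, , drop = FALSE] %*% fit$coefficients)
    out[[paste0(phenotype, "_resid")]] <- resid
  }
  twin_cohort(out, phenotypes = cohort_phenotypes(cohort),
              timepoints = cohort_timepoints(cohort),
              provenance = cohort_provenance(cohort))
}

#' Polygenic-score association with cluster-robust inference
#'
#' Population-averaged regression of a phenotype on a standardized
#' polygenic score, adjusting for covariates and the leading ancestry
#' principal components, with cluster-robust standard errors over twin
#' pairs. Both the score and the phenotype are z-scored, so the
#' reported coefficient is a standardized effect size.
#'
#' @param cohort a [twin_cohort()] with score, covariate, and PC
#'   columns.
#' @param score_name column holding the polygenic score.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names (sex, age, flagged
#'   background variables).
#' @param n_pcs number of ancestry PCs to include; columns `pc1`,
#'   `pc2`, ... must exist. Default 10.
#' @param working_structure passed to [fit_gee()].
#' @return A `gee_fit`; the score coefficient is the entry named after
#'   `score_name`.
#' @export
pgs_association <- function(cohort, score_name, phenotype,
                            covariates = character(0), n_pcs = 10,
                            working_structure = "exchangeable") {
  pcs <- if (n_pcs > 0) paste0("pc", seq_len(n_pcs)) else character(0)
  miss <- setdiff(pcs, names(cohort))
  if (length(miss))
    stop("configuration error: missing ancestry PC columns: ",
         paste(miss, collapse = ", "))
  stopifnot(score_name %in% names(cohort), phenotype %in% names(cohort))
  df <- as.data.frame(cohort)
  zscore <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  df[[score_name]] <- zscore(df[[score_name]])
  y <- zscore(df[[phenotype]])
  X <- design_matrix(df, c(score_name, covariates, pcs))
  fit_gee(y, X, df$pair_id, working_structure = working_structure)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m_tests`, reported exactly and rounded to three decimals
#' (the conventional reporting precision).
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param m_tests number of tests in the family.
#' @return List with `threshold` and `rounded`.
#' @examples
#' bonferroni_threshold(0.05, 14)  # 0.00357..., reported as .004
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  if (m_tests <= 0) stop("invalid input: m_tests must be positive")
  thr <- alpha / m_tests
  list(threshold = thr, rounded = round(thr, 3))
}
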