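#' Path coefficients for a univariate ACE twin model
#'
#' Bundles the path coefficients of the classical univariate twin model:
#' additive genetic (`a`), shared environment (`c`), unique environment
#' (`e`, which absorbs measurement error and must be strictly positive),
#' and an optional sibling-interaction / rater-contrast coefficient `s`.
#' Paths are on the phenotype standard-deviation scale; `s` is
#' dimensionless. Squared paths give variance components, so the sign of
#' `a` and `c` is not identified and only magnitudes matter.
#'
#' The sibling interaction lets each twin's phenotype feed linearly into
#' the co-twin's with weight `s`; `|s| < 1` is required so that the
#' interaction system `(I - B)` is invertible.
#'
#' @param a additive-genetic path coefficient.
#' @param c shared-environment path coefficient.
#' @param e unique-environment path coefficient; must be non-zero
#'   (its square is the E variance component).
#' @param s sibling-interaction coefficient, `|s| < 1`. Default 0.
#' @return An object of class `ace_params`.
#' @examples
#' p <- ace_params(a = sqrt(0.3), c = sqrt(0.61), e = sqrt(0.09))
#' pair_covariance(p, "MZ")
#' @seealso [pair_covariance()], [simulate_univariate_cohort()]
#' @export
ace_params <- function(a = 0, c = 0, e = 1, s = 0) {
  stopifnot(is.numeric(a), is.numeric(c), is.numeric(e), is.numeric(s),
            length(a) == 1L, length(c) == 1L, length(e) == 1L, length(s) == 1L)
  if (!is.finite(e) || e^2 <= 0)
    stop("invalid parameter: 'e' must be non-zero (E includes measurement error)")
  if (!is.finite(s) || abs(s) >= 1)
    stop("singular interaction: |s| must be < 1")
  structure(list(a = a, c = c, e = e, s = s), class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  tot <- x$a^2 + x$c^2 + x$e^2
  cat("ACE twin-model parameters\n")
  cat(sprintf("  paths: a = %.4g, c = %.4g, e = %.4g, s = %.4g\n",
              x$a, x$c, x$e, x$s))
  cat(sprintf("  standardized: A = %.3f, C = %.3f, E = %.3f\n",
              x$a^2 / tot, x$c^2 / tot, x$e^2 / tot))
  invisible(x)
}

#' Path coefficients for a bivariate longitudinal Cholesky decomposition
#'
#' Parameters of the two-timepoint Cholesky twin model. For each source
#' X in {A, C, E} there are three paths: `x1` loads the first-timepoint
#' phenotype on the timepoint-1 factor, `xb` carries that factor over to
#' the second timepoint, and `xu` loads a factor unique to timepoint 2.
#' Squared paths standardized by the per-timepoint totals give the
#' proportions of variance that are carried over versus age-specific.
#' Optional sibling-interaction coefficients `s1` and `s2` act within
#' each timepoint (co-twin phenotype feedback), mirroring the univariate
#' construction.
#'
#' @param a1,ab,au additive-genetic paths (timepoint 1, carryover, unique).
#' @param c1,cb,cu shared-environment paths.
#' @param e1,eb,eu unique-environment paths; `e1` and `eu` must be
#'   non-zero.
#' @param s1,s2 within-timepoint sibling-interaction coefficients,
#'   `|s| < 1`. Default 0.
#' @return An object of class `cholesky_params`.
#' @examples
#' cp <- cholesky_params(a1 = 0.5, ab = 0.3, au = 0.4,
#'                       e1 = sqrt(1 - 0.25), eb = 0, eu = sqrt(1 - 0.25))
#' implied_covariance_4x4(cp, "DZ")
#' @export
cholesky_params <- function(a1 = 0, ab = 0, au = 0,
                            c1 = 0, cb = 0, cu = 0,
                            e1 = 1, eb = 0, eu = 1,
                            s1 = 0, s2 = 0) {
  vals <- c(a1 = a1, ab = ab, au = au, c1 = c1, cb = cb, cu = cu,
            e1 = e1, eb = eb, eu = eu, s1 = s1, s2 = s2)
  stopifnot(all(vapply(vals, is.numeric, logical(1))), all(is.finite(vals)))
  if (e1^2 <= 0 || eu^2 <= 0)
    stop("invalid parameter: 'e1' and 'eu' must be non-zero")
  if (abs(s1) >= 1 || abs(s2) >= 1)
    stop("singular interaction: |s1| and |s2| must be < 1")
  structure(as.list(vals), class = "cholesky_params")
}

#' @export
print.cholesky_params <- function(x, ...) {
  cat("Bivariate Cholesky twin-model parameters\n")
  cat(sprintf("  A: a1 = %.4g, ab = %.4g, au = %.4g\n", x$a1, x$ab, x$au))
  cat(sprintf("  C: c1 = %.4g, cb = %.4g, cu = %.4g\n", x$c1, x$cb, x$cu))
  cat(sprintf("  E: e1 = %.4g, eb = %.4g, eu = %.4g\n", x$e1, x$eb, x$eu))
  if (x$s1 != 0 || x$s2 != 0)
    cat(sprintf("  sibling interaction: s1 = %.4g, s2 = %.4g\n", x$s1, x$s2))
  invisible(x)
}

# Genetic correlation between co-twins by zygosity (MZ share all
# segregating DNA, DZ on average half).
zygosity_rho <- function(zygosity) {
  z <- toupper(as.character(zygosity))
  if (!all(z %in% c("MZ", "DZ"))) stop("zygosity must be 'MZ' or 'DZ'")
  ifelse(z == "MZ", 1, 0.5)
}

# Apply the sibling-interaction transform Sigma = (I-B)^-1 Su (I-B)^-T,
# where B couples phenotypes within the blocks listed in `blocks`
# (each block: indices of the two coupled variables) with coefficient s.
interaction_transform <- function(Sigma_u, s, blocks) {
  k <- nrow(Sigma_u)
  B <- matrix(0, k, k)
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    B[bl[1], bl[2]] <- B[bl[2], bl[1]] <- s[i]
  }
  M <- solve(diag(k) - B)
  M %*% Sigma_u %*% t(M)
}

#' Implied covariance of a twin pair under the ACE(-s) model
#'
#' Computes the 2x2 covariance matrix of the two co-twins' phenotypes
#' implied by a set of ACE path coefficients. Before any interaction, the
#' diagonal is \eqn{a^2 + c^2 + e^2} and the off-diagonal is
#' \eqn{\rho a^2 + c^2} with \eqn{\rho = 1} for MZ and \eqn{0.5} for DZ
#' pairs. When the sibling-interaction coefficient `s` is non-zero the
#' base covariance \eqn{\Sigma_u} is transformed to
#' \eqn{(I-B)^{-1} \Sigma_u (I-B)^{-\top}} with \eqn{B} holding `s` on
#' the off-diagonal; this makes the total variance zygosity-dependent,
#' which is the empirical signature of sibling interaction or rater
#' contrast.
#'
#' @param params an [ace_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive-definite 2x2 matrix.
#' @examples
#' pair_covariance(ace_params(a = sqrt(0.3), c = sqrt(0.61),
#'                            e = sqrt(0.09)), "MZ")
#' @export
pair_covariance <- function(params, zygosity) {
  if (!inherits(params, "ace_params"))
    params <- do.call(ace_params, as.list(params))
  rho <- zygosity_rho(zygosity)
  v <- params$a^2 + params$c^2 + params$e^2
  cv <- rho * params$a^2 + params$c^2
  Sigma_u <- matrix(c(v, cv, cv, v), 2, 2)
  if (params$s == 0) return(Sigma_u)
  interaction_transform(Sigma_u, params$s, list(c(1L, 2L)))
}

#' Implied 4x4 pair covariance of the bivariate Cholesky model
#'
#' Covariance of the vector (twin1-t1, twin2-t1, twin1-t2, twin2-t2)
#' implied by [cholesky_params()]. Within-twin blocks sum the A, C, and E
#' 2x2 time-covariances (e.g. the A block has entries \eqn{a_1^2},
#' \eqn{a_1 a_b}, and \eqn{a_b^2 + a_u^2}); cross-twin blocks weight the
#' genetic block by \eqn{\rho} (1 for MZ, 0.5 for DZ) and include the C
#' block at full weight, while E contributes nothing across twins. If
#' `s1` or `s2` is non-zero the interaction transform is applied with the
#' coupling acting within each timepoint.
#'
#' @param params a [cholesky_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive-definite 4x4 matrix with rows/columns
#'   ordered twin1-t1, twin2-t1, twin1-t2, twin2-t2.
#' @export
implied_covariance_4x4 <- function(params, zygosity) {
  if (!inherits(params, "cholesky_params"))
    params <- do.call(cholesky_params, as.list(params))
  rho <- zygosity_rho(zygosity)
  comp2 <- function(x1, xb, xu)
    matrix(c(x1^2, x1 * xb, x1 * xb, xb^2 + xu^2), 2, 2)
  A2 <- comp2(params$a1, params$ab, params$au)
  C2 <- comp2(params$c1, params$cb, params$cu)
  E2 <- comp2(params$e1, params$eb, params$eu)
  within <- A2 + C2 + E2
  cross <- rho * A2 + C2
  # index of (twin i, time t) in the 4-vector
  ix <- function(i, t) (t - 1L) * 2L + i
  Sigma_u <- matrix(0, 4, 4)
  for (i in 1:2) for (j in 1:2) for (t1 in 1:2) for (t2 in 1:2) {
    blk <- if (i == j) within else cross
    Sigma_u[ix(i, t1), ix(j, t2)] <- blk[t1, t2]
  }
  if (params$s1 != 0 || params$s2 != 0) {
    Sigma_u <- interaction_transform(Sigma_u, c(params$s1, params$s2),
                                     list(c(1L, 2L), c(3L, 4L)))
  }
  ev <- eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("invalid parameter: implied pair covariance is not positive definite")
  Sigma_u
}
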