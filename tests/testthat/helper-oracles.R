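# Brute-force path-equation simulation of twin pairs: each twin's
# phenotype is P = (I - B)^-1 (aA + cC + eE) with A correlated rho
# across twins, C shared, E independent. Independent of the package's
# matrix-based construction; used as a simulation oracle.
simulate_path_equations <- function(a, c, e, s, rho, n, seed) {
  set.seed(seed)
  # genetic deviates with correlation rho across twins
  A1 <- rnorm(n); A2 <- rho * A1 + sqrt(1 - rho^2) * rnorm(n)
  C <- rnorm(n)
  E1 <- rnorm(n); E2 <- rnorm(n)
  u1 <- a * A1 + c * C + e * E1
  u2 <- a * A2 + c * C + e * E2
  Minv <- solve(diag(2) - matrix(c(0, s, s, 0), 2, 2))
  t(Minv %*% rbind(u1, u2))
}

# Double-entry Pearson correlation (each pair entered in both orders),
# the classical estimator of the intraclass twin correlation.
double_entry_cor <- function(m) {
  stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]),
             use = "complete.obs")
}

study_ace <- function() ace_params(sqrt(0.30), sqrt(0.61), sqrt(0.09))
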