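# Full-information ML machinery for multivariate-normal pair data.
#
# Rows with arbitrary missingness patterns are grouped by pattern and
# summarized once (count, mean, scatter), so each likelihood evaluation
# costs O(#patterns) regardless of sample size. Incomplete pairs
# contribute the marginal normal likelihood of their observed cells.

fiml_stats <- function(Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(Y) == 0)
    return(structure(list(patterns = list(), n_rows = 0L, n_obs = 0L,
                          p = ncol(Y)), class = "fiml_stats"))
  pat <- apply(obs, 1, function(o) paste(which(o), collapse = ","))
  patterns <- lapply(split(seq_len(nrow(Y)), pat), function(idx) {
    cols <- which(obs[idx[1], ])
    Yp <- Y[idx, cols, drop = FALSE]
    m <- colMeans(Yp)
    list(cols = cols, n = length(idx), mean = m,
         scatter = crossprod(sweep(Yp, 2, m)))
  })
  structure(list(patterns = patterns, n_rows = nrow(Y),
                 n_obs = sum(obs), p = ncol(Y)),
            class = "fiml_stats")
}

# -2 log likelihood of N(mu, Sigma) given pattern-grouped statistics.
fiml_neg2ll <- function(stats, mu, Sigma) {
  tot <- 0
  for (st in stats$patterns) {
    cols <- st$cols
    S <- Sigma[cols, cols, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- st$mean - mu[cols]
    tot <- tot + st$n * (length(cols) * log(2 * pi) + logdet +
                           drop(crossprod(d, Sinv %*% d))) +
      sum(Sinv * st$scatter)
  }
  tot
}

# Minimize fn with several starting vectors; returns the best optim fit
# plus a convergence flag (gradient norm and agreement across starts).
multi_start_optim <- function(starts, fn, reltol = 1e-12) {
  best <- NULL
  for (par0 in starts) {
    res <- tryCatch(
      stats::optim(par0, fn, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    # polish with Nelder-Mead in case BFGS stalled on a kink
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimization failed from every start")
  grad <- numeric_gradient(fn, best$par)
  gtol <- max(1e-3, 1e-5 * abs(best$value))  # scale with the -2LL
  best$converged <- best$convergence == 0 &&
    all(is.finite(grad)) && sqrt(sum(grad^2)) < gtol
  best
}

numeric_gradient <- function(fn, par, h = 1e-6) {
  f0 <- fn(par)
  vapply(seq_along(par), function(i) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, numeric(1))
}

numeric_hessian <- function(fn, par, h = 1e-4) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    pp <- function(di, dj) {
      p <- par; p[i] <- p[i] + di * h; p[j] <- p[j] + dj * h; fn(p)
    }
    H[i, j] <- H[j, i] <-
      (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) / (4 * h^2)
  }
  H
}
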