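# Independent oracles used across tests. These deliberately avoid the
# package's own closed forms: fine-grained numerical integration for AFDs,
# normal equations and leave-one-out refits for OLS influence, and the
# textbook pooling formulas written out directly.

# AFD by fine Riemann discretization of the linearly interpolated weight.
afd_bruteforce <- function(b0, b1, b2, period_days = c(122, 122), k = 20000) {
  w <- bai_to_afd_weight(c(b0, b1, b2))
  seg <- function(wa, wb, d) {
    t <- (seq_len(k) - 0.5) / k
    sum(wa + (wb - wa) * t) * d / k
  }
  seg(w[1], w[2], period_days[1]) + seg(w[2], w[3], period_days[2])
}

# OLS coefficients by explicit normal equations.
ols_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Leave-one-out influence oracle: refit without each observation.
loo_influence <- function(X, y) {
  full <- ols_normal_equations(X, y)
  n <- nrow(X)
  p <- ncol(X)
  res <- y - drop(X %*% full)
  s2 <- sum(res^2) / (n - p)
  cooks <- numeric(n)
  dfb <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n)) {
    bi <- ols_normal_equations(X[-i, , drop = FALSE], y[-i])
    d <- full - bi
    cooks[i] <- drop(t(d) %*% crossprod(X) %*% d) / (p * s2)
    resi <- y[-i] - drop(X[-i, , drop = FALSE] %*% bi)
    s2i <- sum(resi^2) / (n - 1 - p)
    dfb[i, ] <- d / sqrt(s2i * diag(solve(crossprod(X))))
  }
  list(cooks = cooks, dfbetas = dfb)
}

# Rubin / Barnard-Rubin pooling written out from the textbook formulas.
rubin_oracle <- function(q, u, dfcom = Inf) {
  m <- length(q)
  qbar <- sum(q) / m
  W <- sum(u) / m
  B <- sum((q - qbar)^2) / (m - 1)
  Tt <- W + (1 + 1 / m) * B
  lam <- (1 + 1 / m) * B / Tt
  nu_old <- if (lam > 0) (m - 1) / lam^2 else Inf
  nu <- if (is.finite(dfcom)) {
    nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lam)
    1 / (1 / nu_old + 1 / nu_obs)
  } else nu_old
  list(estimate = qbar, W = W, B = B, T = Tt, df = nu,
       p = 2 * pt(-abs(qbar / sqrt(Tt)), nu))
}

# A small, fast synthetic-trial configuration for unit tests.
test_config <- function(n = 60, seed = 11, ...) {
  trial_config(n_treat = n, n_control = n, seed = seed, ...)
}

# Complete-data imputation set (identical completions) for screening tests.
complete_imps <- function(trial, m = 2) {
  em_bootstrap_impute(trial, m = m, seed = 99)
}
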