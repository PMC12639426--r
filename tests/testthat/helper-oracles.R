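# Independent oracles used by the test suite. These are coded separately
# from the package internals (loops and direct formulas, no shared helpers)
# so that agreement is evidence of correctness, not of shared bugs.

# Trapezoidal integral by explicit segment summation.
trapz_oracle <- function(t_min, values) {
  s <- 0
  for (i in seq_len(length(t_min) - 1)) {
    s <- s + (t_min[i + 1] - t_min[i]) * (values[i] + values[i + 1]) / 2
  }
  s
}

# Split-chain potential-scale-reduction factor, coded directly from the
# published formula with explicit loops.
rhat_oracle <- function(chains) {
  n <- floor(length(chains[[1]]) / 2)
  halves <- list()
  for (ch in chains) {
    halves[[length(halves) + 1]] <- ch[1:n]
    halves[[length(halves) + 1]] <- ch[(length(ch) - n + 1):length(ch)]
  }
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  W <- mean(vapply(halves, var, 0))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Exact marginal posterior mean/SD of the regression coefficients under the
# semi-conjugate model y ~ N(Xb, s2 I), b ~ N(0, beta_sd^2 I),
# s2 ~ IG(a, r), by quadrature over log(s2):
#   p(s2 | y) prop. to N(y; 0, s2 I + beta_sd^2 X X') * IG(s2; a, r)
#   E[b | y]   = sum_k w_k m(s2_k)
#   Var[b | y] = sum_k w_k (V(s2_k) + m m') - E E'   (law of total variance)
semiconj_oracle <- function(X, y, beta_sd = 100, a = 0.001, r = 0.001,
                            nquad = 600) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  s2hat <- sum(lm.fit(X, y)$residuals^2) / max(n - p, 1)
  ls2_grid <- seq(log(s2hat) - 5, log(s2hat) + 5, length.out = nquad)
  logw <- numeric(nquad)
  ms <- matrix(0, p, nquad)
  Vs <- array(0, c(p, p, nquad))
  for (k in seq_len(nquad)) {
    s2 <- exp(ls2_grid[k])
    Sigma <- s2 * diag(n) + beta_sd^2 * tcrossprod(X)
    L <- chol(Sigma)
    q <- backsolve(L, y, transpose = TRUE)
    logw[k] <- -sum(log(diag(L))) - 0.5 * sum(q^2) - a * ls2_grid[k] - r / s2
    V <- solve(XtX / s2 + diag(1 / beta_sd^2, p))
    ms[, k] <- V %*% Xty / s2
    Vs[, , k] <- V
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  Em <- as.vector(ms %*% w)
  EV <- matrix(0, p, p)
  for (k in seq_len(nquad)) {
    EV <- EV + w[k] * (Vs[, , k] + tcrossprod(ms[, k]))
  }
  Cov <- EV - tcrossprod(Em)
  list(mean = Em, sd = sqrt(diag(Cov)))
}
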