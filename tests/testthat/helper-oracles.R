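# Independent oracles used across the suite.

# Two-way ANOVA mean-squares ICC oracle: rows = time points (targets),
# columns = subjects (raters).
icc_anova_oracle <- function(X) {
  n <- nrow(X); M <- ncol(X)
  g <- mean(X); rm <- rowMeans(X); cm <- colMeans(X)
  SSR <- M * sum((rm - g)^2)
  SSC <- n * sum((cm - g)^2)
  SSE <- sum((X - g)^2) - SSR - SSC
  BMS <- SSR / (n - 1)
  JMS <- SSC / (M - 1)
  EMS <- SSE / ((n - 1) * (M - 1))
  c(icc2 = (BMS - EMS) / (BMS + (JMS - EMS) / n),
    icc3 = (BMS - EMS) / BMS)
}

# Explicit transform-matrix route for the consistency variance: builds the
# duplication/elimination matrices and the full M^2 x M^2 Kronecker product.
varC_explicit_oracle <- function(S, n) {
  M <- nrow(S)
  G <- duplication_matrix(M)
  K <- elimination_matrix(M)
  one <- rep(1, M)
  s <- sum(S); tS <- sum(diag(S))
  eta <- (M / ((M - 1) * s^2)) *
    t(-s * as.vector(diag(M)) + tS * kronecker(one, one)) %*% G
  drop(2 / n * eta %*% K %*% (S %x% S) %*% t(K) %*% t(eta))
}

# Gaussian sampler with compound-symmetric subject covariance.
rcs_matrix <- function(n, M, rho) {
  L <- chol(rho * matrix(1, M, M) + (1 - rho) * diag(M))
  matrix(rnorm(n * M), n, M) %*% L
}

# Random subject-time matrix with shared signal, offsets and noise.
rstm <- function(n, M, shared = 1, offset = 0.5, noise = 1) {
  x <- rnorm(n)
  sapply(seq_len(M), function(i)
    shared * x + rnorm(n, sd = noise) + rnorm(1, sd = offset))
}
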