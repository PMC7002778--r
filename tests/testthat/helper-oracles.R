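# Independent oracles used across the suite.

# Closed-form PLS1 coefficients from the Krylov-space representation:
# b = R (R' X'X R)^{-1} R' X'y with R = [s, (X'X)s, ..., (X'X)^{l-1}s],
# s = X'y, on centered data. Algebraically equivalent to NIPALS PLS1.
krylov_pls1 <- function(X, y, l) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  G <- crossprod(Xc)
  R <- s
  v <- s
  if (l > 1) for (k in 2:l) {
    v <- G %*% v
    R <- cbind(R, v)
  }
  as.vector(R %*% solve(t(R) %*% G %*% R, t(R) %*% s))
}

# Brute-force Gaussian kernel by double loop.
gauss_brute <- function(A, B, s2) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    K[i, j] <- exp(-sum((A[i, ] - B[j, ])^2) / s2)
  K
}

# Small linear calibration problem with optional contamination.
make_linear_data <- function(n = 60, m = 3, sd = 0.3, seed = 1,
                             beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  if (is.null(beta)) beta <- seq_len(m) * c(1, -1)[1 + seq_len(m) %% 2]
  y <- as.vector(X %*% beta) + rnorm(n, 0, sd)
  list(x = X, y = y, beta = beta)
}
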