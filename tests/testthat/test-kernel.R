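test_that("Gaussian kernel matches its closed form and brute force", {
  set.seed(21)
  A <- matrix(rnorm(18), 6, 3); B <- matrix(rnorm(12), 4, 3)
  expect_equal(gaussian_kernel(A, B, 2.5), gauss_brute(A, B, 2.5),
               tolerance = 1e-12)
  K <- gaussian_kernel(A, A, 2.5)
  expect_equal(diag(K), rep(1, 6))
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(sqrt(2.5), 0, 0), 1)
  expect_equal(as.numeric(gaussian_kernel(a, b, 2.5)), exp(-1))
  expect_error(gaussian_kernel(A, B, -1), "positive")
  expect_error(gaussian_kernel(A, B[, 1:2], 1), "columns")
})

test_that("automatic bandwidth equals the total predictor variance", {
  set.seed(22)
  x1 <- matrix(rnorm(30, sd = 2), ncol = 1)
  expect_equal(resolve_sigma2(x1), var(x1[, 1]))
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(resolve_sigma2(X), sum(apply(X, 2, var)))
  expect_equal(resolve_sigma2(3 * X), 9 * resolve_sigma2(X))
  Xs <- scale(X)
  expect_equal(resolve_sigma2(Xs), 3, tolerance = 1e-12)
  expect_error(resolve_sigma2(matrix(1, 5, 2)), "variance")
})

test_that("kernel centering follows the double-centering identities", {
  set.seed(23)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  K <- tcrossprod(X)
  cen <- center_kernel(K)
  expect_lt(max(abs(rowSums(cen$Kc))), 1e-8)
  expect_lt(max(abs(colSums(cen$Kc))), 1e-8)
  # idempotence
  expect_equal(center_kernel(cen$Kc)$Kc, cen$Kc, tolerance = 1e-10)
  # all-ones kernel centers to zero
  expect_equal(center_kernel(matrix(1, 5, 5))$Kc, matrix(0, 5, 5))
  # linear kernel of column-centered X is already centered
  Xc <- scale(X, scale = FALSE)
  Kc0 <- tcrossprod(Xc)
  expect_equal(center_kernel(Kc0)$Kc, Kc0, tolerance = 1e-10)
  # PSD preserved up to roundoff
  Kg <- gaussian_kernel(X, X, 3)
  ev <- eigen(center_kernel(Kg)$Kc, symmetric = TRUE, only.values = TRUE)
  expect_gte(min(ev$values), -1e-8)
  # test-block centering agrees with centering the training block itself
  cg <- center_kernel(Kg)
  expect_equal(center_kernel_test(Kg, cg$stats), cg$Kc, tolerance = 1e-10)
})

test_that("kernel PLS with a linear kernel reproduces linear PLS", {
  dat <- make_linear_data(n = 25, m = 4, sd = 0.4, seed = 24)
  d <- regression_dataset(dat$x, dat$y)
  for (l in c(1, 3)) {
    m_lin <- nipals_fit(d, l = l)
    m_k <- kpls_fit(d, l = l, spec = kernel_spec("linear"))
    expect_equal(predict(m_k, dat$x), m_lin$fitted, tolerance = 1e-6)
    Xn <- matrix(rnorm(20), 5, 4)
    expect_equal(predict(m_k, Xn), predict(m_lin, Xn), tolerance = 1e-6)
  }
})

test_that("kernel NIPALS satisfies its structural contracts", {
  set.seed(25)
  X <- matrix(rnorm(40), 20, 2)
  y <- sin(X[, 1]) + rnorm(20, 0, 0.1)
  d <- regression_dataset(X, y)
  km <- kpls_fit(d, l = 4, spec = kernel_spec("gaussian", 2))
  expect_lt(max(abs(crossprod(km$V) - diag(4))), 1e-8)
  # prediction on the training rows reproduces the fitted values path
  expect_equal(predict(km, X),
               as.vector(km$Kc %*% km$dual_coef) + km$y_center,
               tolerance = 1e-8)
  # duplicated test rows give duplicated predictions
  p <- predict(km, X[c(3, 3, 5), ])
  expect_equal(p[1], p[2])
  # full-rank limit interpolates the training response
  km_full <- suppressWarnings(kpls_fit(regression_dataset(X[1:10, ], y[1:10]),
                                       l = 9, spec = kernel_spec("gaussian", 2)))
  expect_equal(predict(km_full, X[1:10, ]), y[1:10], tolerance = 1e-8)
  # score projection reproduces the training scores
  expect_equal(unname(kpls_scores(km, X)), unname(km$V), tolerance = 1e-8)
})

test_that("zero weights in a kernel fit equal physical row deletion", {
  set.seed(26)
  X <- matrix(rnorm(36), 18, 2)
  y <- cos(X[, 2]) + rnorm(18, 0.05)
  d <- regression_dataset(X, y)
  w <- rep(1, 18); w[c(4, 13)] <- 0
  spec <- kernel_spec("gaussian", 1.5)
  f_w <- kpdrgp:::kernel_pls_engine(d, l = 3, spec = spec, w = w)
  f_d <- kpls_fit(regression_dataset(X[w > 0, ], y[w > 0]), l = 3,
                  spec = spec)
  Xn <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(f_w, Xn), predict(f_d, Xn), tolerance = 1e-10)
})
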