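test_that("MVE finds the main cloud under contamination", {
  set.seed(8)
  V <- rbind(matrix(rnorm(180), 90, 2), matrix(rnorm(20, mean = 10), 10, 2))
  est <- mve_fit(V, n_trials = 500, seed = 3)
  expect_lt(sqrt(sum(est$location^2)),
            sqrt(sum((est$location - 10)^2)))
  expect_lt(sqrt(sum(est$location^2)), 1)
  expect_true(all(eigen(est$shape, symmetric = TRUE)$values > 0))
  # bitwise reproducible for the same seed
  est2 <- mve_fit(V, n_trials = 500, seed = 3)
  expect_identical(est$location, est2$location)
  expect_identical(est$shape, est2$shape)
  # cross-check the location against an independent MVE implementation
  cv <- MASS::cov.rob(V, method = "mve", nsamp = 500)
  expect_lt(sqrt(sum((est$location - cv$center)^2)), 1)
})

test_that("MVE works in one dimension and distances are affine invariant", {
  set.seed(9)
  x <- c(rnorm(45), rnorm(5, mean = 30))
  est <- mve_fit(matrix(x, ncol = 1), n_trials = 300, seed = 2)
  clean <- x[x < 10]
  expect_gte(est$location, quantile(clean, 0.25) - 0.5)
  expect_lte(est$location, quantile(clean, 0.75) + 0.5)
  # affine map with matched seeds leaves distances unchanged
  set.seed(10)
  V <- matrix(rnorm(120), 60, 2)
  A <- matrix(c(2, 1, 0, 3), 2, 2); b <- c(5, -4)
  d1 <- robust_mahalanobis(V, mve_fit(V, 400, seed = 7))
  W <- sweep(V %*% A, 2, b, "+")
  d2 <- robust_mahalanobis(W, mve_fit(W, 400, seed = 7))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("robust Mahalanobis distances match the brute-force form", {
  set.seed(11)
  V <- matrix(rnorm(30), 10, 3)
  est <- list(location = c(1, 0, -1), shape = crossprod(matrix(rnorm(9), 3)))
  d <- robust_mahalanobis(V, est)
  brute <- apply(V, 1, function(v)
    t(v - est$location) %*% solve(est$shape) %*% (v - est$location))
  expect_equal(d, unname(brute), tolerance = 1e-10)
  expect_equal(robust_mahalanobis(matrix(est$location, 1), est), 0)
  expect_equal(robust_mahalanobis(matrix(c(2, 0, -1), 1),
                                  list(location = c(1, 0, -1),
                                       shape = diag(3))), 1)
})

test_that("distance cut-off follows median + 3 raw MAD", {
  expect_equal(rmd_cutoff(1:9), 5 + 3 * 2)
  expect_equal(rmd_cutoff(rep(4, 10)), 4)
  set.seed(12)
  v <- rchisq(50, 3)
  expect_equal(rmd_cutoff(v), rmd_cutoff(sample(v)))
})

test_that("generalized potentials satisfy the hat-matrix identities", {
  set.seed(13)
  V <- matrix(rnorm(20), 10, 2)
  p0 <- generalized_potentials(V)
  w0 <- attr(p0, "w_del")
  expect_equal(sum(w0), 2, tolerance = 1e-8)           # trace = l
  expect_equal(as.numeric(p0), w0 / (1 - w0), tolerance = 1e-10)
  # single-deletion identity: w_ii^(-i) = w_ii / (1 - w_ii)
  for (i in c(1, 4, 7)) {
    wi <- attr(generalized_potentials(V, D = i), "w_del")[i]
    expect_equal(wi, w0[i] / (1 - w0[i]), tolerance = 1e-8)
  }
  # group-deletion recursion w^(-(D+i)) = w^(-D) / (1 - w^(-D))
  D <- c(2, 9)
  wD <- attr(generalized_potentials(V, D = D), "w_del")
  for (i in setdiff(1:10, D)) {
    wDi <- attr(generalized_potentials(V, D = c(D, i)), "w_del")[i]
    expect_equal(wDi, wD[i] / (1 - wD[i]), tolerance = 1e-8)
  }
  # duplicated retained rows share the same potential
  V2 <- rbind(V, V[5, ])
  p2 <- generalized_potentials(V2, D = 2)
  expect_equal(p2[5], p2[11], tolerance = 1e-10)
  expect_error(generalized_potentials(V, D = 1:9), "shrink")
})

test_that("potential cut-off uses the printed 0.6475 scaling", {
  expect_equal(potential_cutoff(1:9, c = 3), 5 + 3 * 2 / 0.6475,
               tolerance = 1e-10)
  expect_equal(potential_cutoff(rep(7, 5)), 7)
  p <- rexp(30)
  expect_equal(potential_cutoff(5 * p), 5 * potential_cutoff(p),
               tolerance = 1e-12)
})

test_that("DRGP flags gross leverage and stays moderate on clean scores", {
  # a 10-sigma row is always confirmed
  hits <- 0; nflag <- integer(20)
  for (r in 1:20) {
    set.seed(r + 100)
    V <- matrix(rnorm(300), 100, 3)
    dr0 <- drgp_run(V, seed = r)
    nflag[r] <- sum(dr0$final_flags)
    V[7, ] <- 10 * sqrt(3)
    dr <- drgp_run(V, seed = r)
    if (dr$final_flags[7]) hits <- hits + 1
    expect_true(all(dr$potentials >= 0))
    expect_true(all(which(dr$final_flags) %in% dr$suspects))
    expect_equal(dr$obs_weights, as.numeric(!dr$final_flags))
  }
  expect_equal(hits, 20)
  # null behaviour: median flag count stays a small fraction of n
  expect_lte(median(nflag), 5)
})

test_that("enlarging an outlier's offset never decreases its distance", {
  set.seed(14)
  V <- matrix(rnorm(120), 60, 2)
  est <- mve_fit(V, 400, seed = 1)
  dir <- c(1, 1)
  d_prev <- -Inf
  for (k in c(2, 4, 8, 16)) {
    Vk <- V; Vk[9, ] <- Vk[9, ] + k * dir
    dk <- robust_mahalanobis(Vk, est)[9]
    expect_gt(dk, d_prev)
    d_prev <- dk
  }
})

test_that("PRDRGP refits without confirmed rows and matches deletion", {
  dat <- make_linear_data(n = 80, m = 3, sd = 0.3, seed = 17)
  X <- dat$x; y <- dat$y
  X[c(5, 6, 7), ] <- X[c(5, 6, 7), ] + 8       # leverage cluster
  d <- regression_dataset(X, y)
  fit <- prdrgp_fit(d, robust_pls_config(l = 3, seed = 4))
  flags <- fit$diagnostics$final_flags
  expect_true(all(flags[5:7]))
  keep <- !flags
  m_del <- nipals_fit(regression_dataset(X[keep, ], y[keep]), l = 3)
  expect_equal(fit$model$coef, m_del$coef, tolerance = 1e-10)
  # no flags: identical to plain PLS
  d0 <- regression_dataset(dat$x, dat$y)
  fit0 <- prdrgp_fit(d0, robust_pls_config(l = 3, seed = 4))
  if (!any(fit0$diagnostics$final_flags))
    expect_equal(fit0$model$coef, nipals_fit(d0, l = 3)$coef)
})
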