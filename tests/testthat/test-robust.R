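test_that("weight functions reproduce their closed forms", {
  fair4 <- weight_spec("fair", 4)
  hub <- weight_spec("huber", 1.345)
  expect_equal(weight_fun(0, fair4), 1)
  expect_equal(weight_fun(4, fair4), 0.25)
  expect_equal(weight_fun(1, fair4), 1 / (1 + 1 / 4)^2)
  expect_equal(weight_fun(0, hub), 1)
  expect_equal(weight_fun(2.690, hub), 0.5)
  z <- seq(-30, 30, by = 0.25)
  for (spec in list(fair4, hub)) {
    w <- weight_fun(z, spec)
    expect_true(all(w > 0 & w <= 1))
    expect_true(all(diff(w[z >= 0]) <= 0))      # nonincreasing in |z|
  }
  expect_error(weight_spec("fair", -1), "positive")
})

test_that("scale estimators match hand counts and are consistent", {
  expect_equal(mad_scale(c(1, 2, 3, 4, 100), constant = 1), 1)
  x <- rnorm(50)
  expect_equal(mad_scale(x), mad_scale(-x))
  set.seed(1)
  expect_equal(mad_scale(rnorm(1e5)), 1, tolerance = 0.02)
  # LMS plug-in: n = 25, p = 5, median |r| = 1
  r <- c(rep(-0.5, 12), 1, rep(2, 12))      # median |r| = 1 by construction
  expect_equal(median(abs(r)), 1)
  expect_equal(lms_scale(r, p = 5), 1.85325, tolerance = 1e-10)
  expect_equal(lms_scale(rep(3, 20), p = 2), 1.4826 * (1 + 5 / 18) * 3)
  # trimmed scale: zero for constant residuals, consistent at the normal
  expect_equal(lts_scale(rep(2.5, 30)), 0)
  set.seed(2)
  expect_equal(lts_scale(rnorm(1e4)), 1, tolerance = 0.05)
})

test_that("the spatial median behaves like its geometric definition", {
  expect_equal(l1_median(matrix(c(3, -1), 1, 2)), c(3, -1))
  x <- matrix(c(1, 2, 4, 8, 100), ncol = 1)
  expect_equal(l1_median(x), median(x), tolerance = 1e-6)
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  expect_equal(l1_median(sq), c(0.5, 0.5), tolerance = 1e-6)
  # cross-check against an independent Weiszfeld implementation
  skip_if_not_installed("pracma")
  set.seed(3)
  V <- matrix(rnorm(60), 30, 2)
  expect_equal(l1_median(V), as.vector(pracma::geo_median(V)$p),
               tolerance = 1e-5)
})

test_that("residual and score weights standardize as specified", {
  fair4 <- weight_spec("fair", 4)
  expect_equal(residual_weights(c(0, 4, -4), 1, fair4), c(1, 0.25, 0.25))
  expect_equal(residual_weights(8, 2, fair4), 0.25)
  expect_error(residual_weights(1, 0, fair4), "positive")
  # distant score row gets the smallest weight
  V <- rbind(matrix(rnorm(40, sd = 0.3), 20, 2), c(10, 10))
  w <- score_weights(V, fair4)
  expect_equal(which.min(w), 21)
  expect_true(attr(w, "leverage_flag")[21])
  # standardized distance 1 gives the closed-form fair weight
  expect_equal(unname(sort(w)[11]) > 0.3, TRUE)
  expect_error(score_weights(matrix(1, 5, 2), fair4), "degenerate")
})

test_that("PRM resists vertical outliers and reduces to PLS when clean", {
  dat <- make_linear_data(n = 200, m = 3, sd = 0.5, seed = 11)
  d <- regression_dataset(dat$x, dat$y)
  b_pls <- nipals_fit(d, l = 3)$coef
  b_prm <- prm_fit(d, robust_pls_config(l = 3))$model$coef
  expect_lt(max(abs(b_prm - b_pls)) / max(abs(b_pls)), 0.05)
  # one gross outlier: PRM closer to truth than PLS in >= 95/100 runs
  wins <- 0
  for (r in 1:100) {
    dat <- make_linear_data(n = 60, m = 3, sd = 0.3, seed = r)
    y <- dat$y; y[5] <- y[5] + 20
    d <- regression_dataset(dat$x, y)
    e_pls <- sqrt(sum((nipals_fit(d, l = 3)$coef - dat$beta)^2))
    e_prm <- sqrt(sum((prm_fit(d, robust_pls_config(l = 3))$model$coef -
                         dat$beta)^2))
    if (e_prm < e_pls) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("PRM iteration keeps weights valid and the objective monitored", {
  dat <- make_linear_data(n = 50, m = 3, seed = 13)
  y <- dat$y; y[c(4, 9)] <- y[c(4, 9)] - 15
  fit <- prm_fit(regression_dataset(dat$x, y), robust_pls_config(l = 3))
  w <- fit$state$weights
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_lt(fit$state$weights[4], 0.05)
  expect_true(is.finite(fit$state$objective))
  # affine equivariance in y: a*y + b maps coefficients to a*b_coef
  f1 <- prm_fit(regression_dataset(dat$x, dat$y), robust_pls_config(l = 3))
  f2 <- prm_fit(regression_dataset(dat$x, 2 * dat$y + 5),
                robust_pls_config(l = 3))
  expect_equal(2 * f1$model$coef, f2$model$coef, tolerance = 1e-3)
})

test_that("PRMM keeps a frozen trimmed scale and high breakdown", {
  dat <- make_linear_data(n = 120, m = 2, sd = 0.3, seed = 21)
  d <- regression_dataset(dat$x, dat$y)
  cfg <- robust_pls_config(l = 2, seed = 1)
  f_clean <- prmm_fit(d, cfg, n_starts = 100)
  b_prm <- prm_fit(d, cfg)$model$coef
  expect_lt(max(abs(f_clean$model$coef - b_prm)) / max(abs(b_prm)), 0.05)
  # final weighted objective at the frozen scale does not exceed stage 1's
  f1 <- dat$y - predict(prm_fit(d, cfg)$model, dat$x)
  s <- f_clean$state$scale
  obj1 <- sum(residual_weights(f1, s, cfg$residual_weight) * f1^2)
  expect_lte(f_clean$state$objective, obj1 + 1e-8)
  # 40% response contamination: slope error < 0.2|b| in >= 90% of runs
  ok <- 0
  for (r in 1:20) {
    set.seed(r + 300)
    n <- 100; X <- matrix(rnorm(n), n, 1)
    y <- 2 * X[, 1] + rnorm(n, 0, 0.2)
    bad <- sample(n, 40); y[bad] <- y[bad] + 15
    f <- prmm_fit(regression_dataset(X, y),
                  robust_pls_config(l = 1, seed = r), n_starts = 200)
    if (abs(f$model$coef - 2) < 0.4) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("GM6 takes one bounded-influence Newton step", {
  # psi effectively linear and unit weights: the step lands on the
  # score-space least-squares solution
  dat <- make_linear_data(n = 40, m = 2, sd = 0.2, seed = 31)
  d <- regression_dataset(dat$x, dat$y)
  g <- gm6_fit(d, robust_pls_config(l = 2, seed = 2), huber_c = 1e6)
  ols <- nipals_fit(d, l = 2)
  expect_equal(predict(g, dat$x), ols$fitted, tolerance = 1e-6)
  # a gross leverage row is downweighted and its pull reduced
  X <- dat$x; y <- dat$y
  X[3, ] <- c(9, 9); y[3] <- -12
  d2 <- regression_dataset(X, y)
  g2 <- gm6_fit(d2, robust_pls_config(l = 2, seed = 2))
  expect_lt(g2$leverage_weights[3], min(g2$leverage_weights[-3]))
  e_gm6 <- sqrt(sum((g2$coef - dat$beta)^2))
  e_pls <- sqrt(sum((nipals_fit(d2, l = 2)$coef - dat$beta)^2))
  expect_lt(e_gm6, e_pls)
})

test_that("trimmed-squares PLS ignores a contaminated minority", {
  set.seed(41)
  n <- 80; X <- matrix(rnorm(n * 2), n, 2)
  y <- as.vector(X %*% c(1, -1)) + rnorm(n, 0, 0.1)
  bad <- 1:25; y[bad] <- y[bad] + 10
  f <- lts_pls_fit(regression_dataset(X, y), l = 2, n_starts = 200,
                   seed = 5)
  expect_lt(max(abs(f$model$coef - c(1, -1))), 0.1)
  expect_lt(f$scale, 0.2)
  # reproducible for a fixed seed
  f2 <- lts_pls_fit(regression_dataset(X, y), l = 2, n_starts = 200,
                    seed = 5)
  expect_identical(f$model$coef, f2$model$coef)
})
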