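#' Specify a bounded weight function for robust reweighting
#'
#' The fair family uses `w(z) = 1 / (1 + |z/c|)^2`; the Huber family uses
#' `w(z) = min(1, c / |z|)`. Both map 0 to 1, take values in (0, 1] and are
#' nonincreasing in `|z|`.
#'
#' @param family `"fair"` or `"huber"`.
#' @param tuning_c positive tuning constant. Defaults: 4 (fair), 1.345
#'   (huber), the conventional values in the partial robust M-regression
#'   literature.
#' @return An object of class `"weight_spec"`.
#' @export
weight_spec <- function(family = c("fair", "huber"), tuning_c = NULL) {
  family <- match.arg(family)
  if (is.null(tuning_c)) tuning_c <- switch(family, fair = 4, huber = 1.345)
  tuning_c <- as.numeric(tuning_c)
  if (!is.finite(tuning_c) || tuning_c <= 0)
    stop_dim("tuning_c must be a positive number")
  structure(list(family = family, tuning_c = tuning_c),
            class = "weight_spec")
}

#' Evaluate a weight function on standardized values
#'
#' @param z numeric vector of standardized residuals or distances.
#' @param spec a [weight_spec()].
#' @return weights in (0, 1].
#' @export
weight_fun <- function(z, spec) {
  stopifnot(inherits(spec, "weight_spec"))
  z <- abs(z); c0 <- spec$tuning_c
  switch(spec$family,
         fair  = 1 / (1 + z / c0)^2,
         huber = pmin(1, ifelse(z > 0, c0 / z, Inf)))
}

#' Median absolute deviation scale
#'
#' `1.4826 * median_i |r_i - median_j r_j|`, the MAD with the usual
#' consistency factor for the normal model. Set `constant = 1` for the raw
#' MAD used by some diagnostic cut-offs.
#'
#' @param residuals numeric vector, length >= 2.
#' @param constant consistency multiplier (default 1.4826).
#' @return nonnegative scalar (0 for a constant vector; callers must guard).
#' @export
mad_scale <- function(residuals, constant = 1.4826) {
  if (length(residuals) < 2) stop_dim("need at least 2 residuals")
  stats::mad(residuals, constant = constant)
}

#' Spatial (geometric) L1-median of multivariate points
#'
#' Weiszfeld iteration minimising the sum of Euclidean distances to the
#' rows of `V`. Points that coincide with the current iterate are handled
#' by the standard modified step (their zero distance is excluded and the
#' step is damped), which preserves convergence.
#'
#' @param V numeric matrix, one point per row.
#' @param tol convergence tolerance on the iterate (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return numeric vector of length `ncol(V)`.
#' @export
l1_median <- function(V, tol = 1e-8, max_iter = 200) {
  V <- as.matrix(V)
  n <- nrow(V)
  if (n == 0) stop_dim("V must have at least one row")
  if (n == 1) return(as.vector(V[1, ]))
  mu <- apply(V, 2, median)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(V, 2, mu)^2))
    at <- d < .Machine$double.eps^0.75
    if (all(at)) break
    inv <- ifelse(at, 0, 1 / pmax(d, .Machine$double.eps))
    mu_new <- as.vector(crossprod(V, inv)) / sum(inv)
    if (any(at)) {
      # damped step when the iterate sits on a data point (Vardi-Zhang)
      r_vec <- as.vector(crossprod(V, inv)) - mu * sum(inv)
      rnorm_ <- sqrt(sum(r_vec^2))
      k <- sum(at)
      if (rnorm_ <= k) break
      mu_new <- mu + (1 - k / rnorm_) * (mu_new - mu)
    }
    if (sqrt(sum((mu_new - mu)^2)) < tol) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  as.vector(mu)
}

#' Residual weights from standardized residuals
#'
#' @param residuals numeric residual vector.
#' @param scale positive robust scale estimate.
#' @param spec a [weight_spec()].
#' @return weights in (0, 1].
#' @export
residual_weights <- function(residuals, scale, spec) {
  if (!is.finite(scale) || scale <= 0) stop_dim("scale must be positive")
  weight_fun(residuals / scale, spec)
}

#' Leverage weights of score rows via distance to the L1-median
#'
#' Each row's Euclidean distance to the spatial median of the scores is
#' standardized by the median distance and passed through the weight
#' function; rows with weight below 0.01 are flagged as suspected high
#' leverage points.
#'
#' @param V score matrix (`n x l`), `n >= 3`.
#' @param spec a [weight_spec()].
#' @return weights in (0, 1] with attribute `"leverage_flag"` (logical).
#' @export
score_weights <- function(V, spec) {
  V <- as.matrix(V)
  if (nrow(V) < 3) stop_dim("need at least 3 score rows")
  ctr <- l1_median(V)
  d <- sqrt(rowSums(sweep(V, 2, ctr)^2))
  md <- median(d)
  if (md <= .Machine$double.eps)
    stop_dim("median score distance is zero; scores are degenerate")
  w <- weight_fun(d / md, spec)
  attr(w, "leverage_flag") <- w < 0.01
  w
}

#' Least-trimmed scale of residuals
#'
#' Consistency-corrected standard deviation of the `h` residuals of
#' smallest magnitude (the half-sample untouched by outliers). The
#' correction divides by the standard deviation of a standard normal
#' truncated to its central `h/n` probability mass, so the estimate is
#' consistent for sigma at the normal model.
#'
#' @param residuals numeric vector, length >= 2.
#' @param h size of the trimmed subset; default `floor((n + l + 1) / 2)`
#'   with `l` taken as 1.
#' @param l number of fitted components, used only for the default `h`.
#' @return nonnegative scalar.
#' @export
lts_scale <- function(residuals, h = NULL, l = 1) {
  n <- length(residuals)
  if (n < 2) stop_dim("need at least 2 residuals")
  if (is.null(h)) h <- floor((n + l + 1) / 2)
  if (h < 2 || h > n) stop_dim("h must be in [2, n]")
  idx <- order(abs(residuals))[seq_len(h)]
  s_raw <- sd(residuals[idx])
  alpha <- h / n
  q <- qnorm((1 + alpha) / 2)
  v_trunc <- 1 - 2 * q * dnorm(q) / alpha
  s_raw / sqrt(v_trunc)
}

#' Least-median-of-squares scale of residuals
#'
#' `1.4826 * (1 + 5 / (n - p)) * median |r_i|`, the finite-sample corrected
#' LMS preliminary scale.
#'
#' @param residuals numeric vector.
#' @param p number of fitted parameters (components).
#' @return nonnegative scalar.
#' @export
lms_scale <- function(residuals, p) {
  n <- length(residuals)
  if (n < 2) stop_dim("need at least 2 residuals")
  if (n <= p) stop_dim("n must exceed p")
  1.4826 * (1 + 5 / (n - p)) * median(abs(residuals))
}

#' Configuration for the robust PLS estimators
#'
#' @param l number of latent components.
#' @param residual_weight [weight_spec()] for standardized residuals
#'   (default fair, c = 4).
#' @param score_weight [weight_spec()] for score-space distances
#'   (default fair, c = 4).
#' @param max_irls_iter cap on reweighting iterations (default 30).
#' @param irls_tol relative coefficient-change convergence tolerance
#'   (default 1e-4).
#' @param seed integer seed for any subsampling performed downstream.
#' @return list of class `"robust_pls_config"`.
#' @export
robust_pls_config <- function(l = 2,
                              residual_weight = weight_spec("fair", 4),
                              score_weight = weight_spec("fair", 4),
                              max_irls_iter = 30, irls_tol = 1e-4,
                              seed = NULL) {
  stopifnot(max_irls_iter >= 1, irls_tol > 0)
  structure(list(l = l, residual_weight = residual_weight,
                 score_weight = score_weight,
                 max_irls_iter = max_irls_iter, irls_tol = irls_tol,
                 seed = seed),
            class = "robust_pls_config")
}

# One IRLS pass shared by PRM and PRMM. `scale_fun(f)` maps current
# residuals to the scale used for standardization (MAD for PRM, frozen
# LTS scale for PRMM).
irls_pls <- function(data, config, scale_fun, w_init = NULL) {
  data <- as_dataset(data)
  n <- data$n
  cfg <- config
  # initial weights from robustly centered response and raw predictor space
  if (is.null(w_init)) {
    f0 <- data$y - median(data$y)
    s0 <- mad_scale(f0)
    wr <- if (s0 > 0) residual_weights(f0, s0, cfg$residual_weight)
          else rep(1, n)
    wx <- tryCatch(as.numeric(score_weights(data$x, cfg$score_weight)),
                   error = function(e) rep(1, n))
    w <- wr * wx
  } else w <- w_init
  w <- pmax(w, 1e-6)

  model <- NULL; b_old <- NULL
  obj <- Inf; best <- NULL; best_obj <- Inf
  converged <- FALSE
  f <- numeric(n); s_hat <- NA_real_
  for (it in seq_len(cfg$max_irls_iter)) {
    model <- weighted_refit(data, w, l = cfg$l)
    f <- data$y - predict(model, data$x)
    s_hat <- scale_fun(f)
    if (!is.finite(s_hat) || s_hat <= 0) { converged <- TRUE; break }
    wr <- residual_weights(f, s_hat, cfg$residual_weight)
    Vall <- pls_scores(model, data$x)
    wx <- tryCatch(as.numeric(score_weights(Vall, cfg$score_weight)),
                   error = function(e) rep(1, n))
    w_new <- pmax(wr * wx, 1e-6)
    obj <- sum(w_new * f^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(model = model, w = w_new, f = f, s = s_hat, it = it)
    }
    b_new <- model$coef
    if (!is.null(b_old)) {
      rel <- sqrt(sum((b_new - b_old)^2)) /
        max(sqrt(sum(b_old^2)), .Machine$double.eps)
      if (rel < cfg$irls_tol) { w <- w_new; converged <- TRUE; break }
    }
    b_old <- b_new
    w <- w_new
  }
  if (is.null(best))
    best <- list(model = model, w = w, f = f, s = s_hat, it = cfg$max_irls_iter)
  state <- structure(list(iteration = best$it, residuals = best$f,
                          scale = best$s, weights = best$w,
                          objective = best_obj, converged = converged),
                     class = "irls_state")
  list(model = best$model, state = state)
}

#' Partial robust M-regression (PRM)
#'
#' Iteratively reweighted PLS1: residual weights from the fair/Huber
#' function of MAD-standardized residuals, multiplied by leverage weights
#' from the distance of each score row to the L1-median of the scores.
#' The generalized weight `w_i = w_i^r * w_i^x` enters the fit through
#' sqrt-weighted rows, minimising `sum_i w_i f_i^2`.
#'
#' @param data a [regression_dataset()].
#' @param config a [robust_pls_config()].
#' @return list with elements `model` (a `"pls_model"`) and `state`
#'   (`"irls_state"`: iteration, residuals, scale, weights, convergence
#'   flag), classed `"robust_pls"`.
#' @export
prm_fit <- function(data, config = robust_pls_config()) {
  out <- irls_pls(data, config, scale_fun = function(f) mad_scale(f))
  structure(c(out, list(method = "prm")), class = "robust_pls")
}

#' Least-trimmed-squares PLS fit by elemental subsampling
#'
#' Approximates the coefficient vector minimising the least-trimmed scale
#' of the PLS1 residuals: random elemental subsets of `l + 1` rows seed
#' candidate fits which are refined by concentration steps (refit on the
#' `h` rows with smallest absolute residuals until the trimmed criterion
#' stops improving); the candidate with the smallest trimmed scale wins.
#' The initial fit on all rows is always included as a candidate.
#'
#' @inheritParams nipals_fit
#' @param h trimming subset size, default `floor((n + l + 1) / 2)`.
#' @param n_starts number of random elemental starts (default 500).
#' @param seed integer seed for the subsampling.
#' @return list with `model` (a `"pls_model"` fitted on the best trimmed
#'   half), `scale` (the minimised [lts_scale()] of its full-data
#'   residuals), `residuals`.
#' @export
lts_pls_fit <- function(data, l, h = NULL, n_starts = 500, seed = 1) {
  data <- as_dataset(data)
  n <- data$n
  if (is.null(h)) h <- floor((n + l + 1) / 2)
  crit <- function(f) sum(sort(f^2)[seq_len(h)])
  c_step <- function(model) {
    # concentration: refit on the h best-fitting rows until stable
    best <- Inf
    for (k in 1:20) {
      f <- data$y - predict(model, data$x)
      cr <- crit(f)
      if (cr >= best - 1e-12) break
      best <- cr
      keep <- as.numeric(rank(abs(f), ties.method = "first") <= h)
      model <- weighted_refit(data, keep, l = l)
    }
    list(model = model, crit = best)
  }
  local_seed(seed, {
    best <- c_step(nipals_fit(data, l = l))
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, min(l + 2, n))
      w0 <- as.numeric(seq_len(n) %in% idx)
      cand <- tryCatch(weighted_refit(data, w0, l = l),
                       error = function(e) NULL)
      if (is.null(cand)) next
      cand <- c_step(cand)
      if (cand$crit < best$crit) best <- cand
    }
    f <- data$y - predict(best$model, data$x)
    list(model = best$model, scale = lts_scale(f, h = h, l = l),
         residuals = f)
  })
}

#' Partial robust MM-regression (PRMM)
#'
#' Three stages: (1) an initial reweighted M-fit (PRM) and a
#' high-breakdown least-trimmed-squares fit ([lts_pls_fit()]) supply
#' candidate residuals; (2) the least-trimmed scale -- minimised over the
#' candidates -- is frozen; (3) the reweighting iteration is rerun with
#' residual weights standardized by the frozen scale (the efficient
#' M-step), leverage weights unchanged. The returned iterate never has a
#' larger weighted objective at the frozen scale than the initial fit.
#'
#' @inheritParams prm_fit
#' @param n_starts elemental starts for the trimmed-squares stage.
#' @return as [prm_fit()], with the frozen scale in `state$scale`.
#' @export
prmm_fit <- function(data, config = robust_pls_config(), n_starts = 500) {
  data <- as_dataset(data)
  stage1 <- prm_fit(data, config)
  f1 <- data$y - predict(stage1$model, data$x)
  lts <- lts_pls_fit(data, l = config$l, n_starts = n_starts,
                     seed = config$seed %||% 1L)
  use_lts <- is.finite(lts$scale) && lts$scale > 0 &&
    (!is.finite(lts_scale(f1, l = config$l)) ||
       lts$scale <= lts_scale(f1, l = config$l))
  s_lts <- if (use_lts) lts$scale else lts_scale(f1, l = config$l)
  f_init <- if (use_lts) lts$residuals else f1
  if (!is.finite(s_lts) || s_lts <= 0) s_lts <- mad_scale(f1)
  if (!is.finite(s_lts) || s_lts <= 0) {
    # exact fit at stage 1; nothing to improve
    return(structure(c(stage1[c("model", "state")], list(method = "prmm")),
                     class = "robust_pls"))
  }
  w0 <- residual_weights(f_init, s_lts, config$residual_weight)
  out <- irls_pls(data, config, scale_fun = function(f) s_lts,
                  w_init = w0)
  # property: final objective at the frozen scale must not exceed stage 1's
  obj1 <- sum(residual_weights(f1, s_lts, config$residual_weight) * f1^2)
  if (out$state$objective > obj1 + 1e-12) {
    out <- stage1
    out$state$scale <- s_lts
  }
  structure(c(out[c("model", "state")], list(method = "prmm")),
            class = "robust_pls")
}

#' Partial robust GM6 regression
#'
#' One-step Newton-Raphson GM-estimator on the PLS score space. A
#' high-breakdown initial fit (PRMM by default) provides starting inner
#' coefficients; leverage weights `w_i = min(1, chisq_{0.95,l} / RM_i^2)`
#' come from MVE-based robust Mahalanobis distances of the score rows; the
#' scale is the LMS preliminary scale of the initial residuals; a single
#' Newton step with the Huber psi-function updates the coefficients:
#' `b = b0 + (V'BV)^{-1} V' [sigma w_i psi(r_i / (sigma w_i))]` with
#' `B = diag(psi'(r_i / (sigma w_i)))`.
#'
#' @inheritParams prm_fit
#' @param huber_c Huber psi tuning constant (default 1.345).
#' @param mve_trials resampling trials for the MVE estimate (default 500).
#' @param initial `"prmm"` (default) or `"lts"`-flavoured start (a plain
#'   PRM fit restricted to the best half by weight).
#' @return a `"pls_model"` with extra fields `leverage_weights`, `rm2`,
#'   `initial_method`, classed `c("gm6_model", "pls_model")`.
#' @export
gm6_fit <- function(data, config = robust_pls_config(), huber_c = 1.345,
                    mve_trials = 500, initial = c("prmm", "lts")) {
  data <- as_dataset(data)
  initial <- match.arg(initial)
  l <- config$l
  base <- nipals_fit(data, l = l)
  V <- unname(pls_scores(base, data$x))      # n x l, centered score space
  yc <- data$y - base$y_center

  # initial inner coefficients from a high-breakdown fit on the scores
  sdat <- regression_dataset(V, yc)
  init_fit <- if (initial == "prmm") prmm_fit(sdat, robust_pls_config(
    l = l, residual_weight = config$residual_weight,
    score_weight = config$score_weight,
    max_irls_iter = config$max_irls_iter, irls_tol = config$irls_tol))
  else {
    f0 <- prm_fit(sdat, robust_pls_config(l = l))
    h <- floor((nrow(V) + l + 1) / 2)
    keep <- order(abs(f0$state$residuals))[seq_len(h)]
    w01 <- as.numeric(seq_len(nrow(V)) %in% keep)
    list(model = weighted_refit(sdat, w01, l = l))
  }
  a0 <- as.vector(init_fit$model$projection %*% init_fit$model$y_loadings)
  ctr <- init_fit$model$x_center
  # express initial fit as yc ~ V a0 + intercept
  ic <- init_fit$model$y_center - sum(ctr * a0)
  r0 <- yc - as.vector(V %*% a0) - ic

  est <- mve_fit(V, n_trials = mve_trials, seed = config$seed %||% 1L)
  rm2 <- robust_mahalanobis(V, est)
  w_lev <- pmin(1, qchisq(0.95, df = l) / pmax(rm2, .Machine$double.eps))
  s_hat <- lms_scale(r0, p = l + 1)
  if (!is.finite(s_hat) || s_hat <= 0) s_hat <- max(mad_scale(r0), 1e-8)

  u <- r0 / (s_hat * w_lev)
  psi <- ifelse(abs(u) <= huber_c, u, huber_c * sign(u))
  dpsi <- as.numeric(abs(u) <= huber_c)
  Vi <- cbind(1, V)                      # intercept updated with the step
  VtBV <- crossprod(Vi, Vi * dpsi)
  rhs <- as.vector(crossprod(Vi, s_hat * w_lev * psi))
  step <- tryCatch(solve(VtBV, rhs), error = function(e) {
    warning("singular V'BV in GM6 step; ridge-regularized solve")
    solve(VtBV + diag(1e-8 * max(diag(VtBV)), l + 1), rhs)
  })
  ic <- ic + step[1]
  a1 <- a0 + step[-1]

  out <- base
  out$coef <- as.vector(base$projection %*% a1)
  out$y_center <- base$y_center + ic   # carry the robust intercept
  out$fitted <- as.vector(sweep(data$x, 2, out$x_center) %*% out$coef) +
    out$y_center
  out$leverage_weights <- w_lev
  out$rm2 <- rm2
  out$initial_method <- initial
  class(out) <- c("gm6_model", "pls_model")
  out
}

#' @export
predict.robust_pls <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
print.robust_pls <- function(x, ...) {
  cat("Robust PLS fit (", toupper(x$method), "): ", x$model$l,
      " component(s); IRLS iterations: ", x$state$iteration,
      if (isTRUE(x$state$converged)) " (converged)" else " (not converged)",
      "\n", sep = "")
  invisible(x)
}
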