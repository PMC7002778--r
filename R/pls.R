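#' Bundle a predictor matrix and response into a calibration dataset
#'
#' Light container pairing an `n x m` predictor matrix (e.g. NIR absorbance
#' spectra, one row per sample) with a single numeric response and optional
#' nonnegative per-observation weights. All fitting functions in the package
#' accept this container.
#'
#' @param x numeric matrix (or coercible), `n` samples by `m` variables.
#' @param y numeric response vector of length `n`.
#' @param obs_weights optional nonnegative weights of length `n`
#'   (default all 1). A weight of zero removes the observation exactly.
#' @return An object of class `"regression_dataset"`: a list with elements
#'   `x`, `y`, `obs_weights`, `n`, `m`.
#' @export
#' @examples
#' d <- regression_dataset(matrix(rnorm(40), 20, 2), rnorm(20))
regression_dataset <- function(x, y, obs_weights = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y))
    stop_dim("nrow(x) [", nrow(x), "] must equal length(y) [", length(y), "]")
  if (anyNA(x) || anyNA(y)) stop_dim("x and y must not contain NA values")
  n <- nrow(x)
  w <- if (is.null(obs_weights)) rep(1, n) else as.numeric(obs_weights)
  if (length(w) != n) stop_dim("obs_weights must have length n")
  if (any(w < 0)) stop_dim("obs_weights must be nonnegative")
  if (all(w == 0)) stop_dim("obs_weights must not be all zero")
  structure(list(x = x, y = y, obs_weights = w, n = n, m = ncol(x)),
            class = "regression_dataset")
}

as_dataset <- function(data) {
  if (inherits(data, "regression_dataset")) return(data)
  if (is.list(data) && !is.null(data$x) && !is.null(data$y))
    return(regression_dataset(data$x, data$y, data$obs_weights))
  stop_dim("expected a regression_dataset (or list with x and y)")
}

#' Fit a PLS1 model by NIPALS with deflation
#'
#' Sequentially extracts `l` latent components from the (weighted-)centered
#' predictor matrix: the weight vector of each component is proportional to
#' `X'y`, scores are `X w`, and `X` and `y` are deflated by the rank-one fit
#' of the scores before the next component. Observation weights `w_i` are
#' honoured by weighted centering and by scaling rows with `sqrt(w_i)`, so
#' the fit minimises the weighted residual sum of squares; zero-weight rows
#' are excluded exactly.
#'
#' @param data a [regression_dataset()] (its `obs_weights` are used).
#' @param l number of latent components, `l <= min(n - 1, m)` counted over
#'   positive-weight rows.
#' @param tol convergence tolerance of the per-component inner loop
#'   (default 1e-4; for a univariate response the loop converges in one
#'   pass, the tolerance only matters for degenerate input).
#' @param max_iter inner-loop iteration cap.
#' @return Object of class `"pls_model"` with elements `coef` (`m`-vector of
#'   regression coefficients on centered data), `x_center`, `y_center`,
#'   `weights` (`m x l` matrix `W`, unit-norm columns), `loadings` (`P`),
#'   `y_loadings` (`q`), `scores` (`n x l`, scores of the sqrt-weight scaled
#'   rows), `projection` (`W (P'W)^{-1}`, maps centered rows to scores),
#'   `fitted` (on the original rows), `l`, `obs_weights`.
#' @export
nipals_fit <- function(data, l, tol = 1e-4, max_iter = 500) {
  data <- as_dataset(data)
  n <- data$n; m <- data$m
  w_obs <- data$obs_weights
  n_eff <- sum(w_obs > 0)
  if (l < 1) stop_dim("l must be >= 1")
  if (l > min(n_eff - 1, m))
    stop_dim("l = ", l, " exceeds min(n_eff - 1, m) = ", min(n_eff - 1, m))

  wn <- w_obs / sum(w_obs)
  x_center <- as.vector(crossprod(data$x, wn))
  y_center <- sum(wn * data$y)
  sw <- sqrt(w_obs)
  Xc <- sweep(data$x, 2, x_center) * sw
  yc <- (data$y - y_center) * sw
  if (sum(yc^2) < 1e-24) stop_dim("response has zero (weighted) variance")

  W <- matrix(0, m, l); P <- matrix(0, m, l); V <- matrix(0, n, l)
  q <- numeric(l)
  X <- Xc; y <- yc
  l_used <- 0L
  for (g in seq_len(l)) {
    u <- y
    wv <- as.vector(crossprod(X, u))
    for (it in seq_len(max_iter)) {
      nw <- sqrt(sum(wv^2))
      if (nw < 1e-12) break
      wv <- wv / nw
      v <- as.vector(X %*% wv)
      # univariate y: u is fixed, so one pass suffices
      wv_new <- as.vector(crossprod(X, u))
      if (sqrt(sum((wv_new / sqrt(sum(wv_new^2)) - wv)^2)) < tol) break
      wv <- wv_new
    }
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) {
      warning("degenerate component ", g, ": stopping at ", g - 1L,
              " components")
      break
    }
    wv <- wv / nw
    # deterministic sign: largest-magnitude weight entry positive
    if (wv[which.max(abs(wv))] < 0) wv <- -wv
    v <- as.vector(X %*% wv)
    vv <- sum(v^2)
    if (vv < 1e-24) {
      warning("degenerate score ", g, ": stopping at ", g - 1L, " components")
      break
    }
    p <- as.vector(crossprod(X, v)) / vv
    qg <- sum(y * v) / vv
    X <- X - tcrossprod(v, p)
    y <- y - v * qg
    W[, g] <- wv; P[, g] <- p; V[, g] <- v; q[g] <- qg
    l_used <- g
  }
  if (l_used == 0L) stop_dim("no non-degenerate component could be extracted")
  W <- W[, seq_len(l_used), drop = FALSE]
  P <- P[, seq_len(l_used), drop = FALSE]
  V <- V[, seq_len(l_used), drop = FALSE]
  q <- q[seq_len(l_used)]

  R <- W %*% solve(crossprod(P, W))       # projection: scores = Xc %*% R
  b <- as.vector(R %*% q)
  fitted <- as.vector(sweep(data$x, 2, x_center) %*% b) + y_center
  structure(list(coef = b, x_center = x_center, y_center = y_center,
                 weights = W, loadings = P, y_loadings = q, scores = V,
                 projection = R, fitted = fitted, l = l_used,
                 obs_weights = w_obs, residual_x = X),
            class = "pls_model")
}

#' Predict from a fitted linear PLS model
#'
#' @param object a `"pls_model"`.
#' @param newdata numeric matrix with the training number of columns (a
#'   single profile may be given as a vector).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop_dim("newdata has ", ncol(newdata), " columns; model expects ",
             length(object$x_center))
  as.vector(sweep(newdata, 2, object$x_center) %*% object$coef) +
    object$y_center
}

#' Project observations into the latent score space of a PLS model
#'
#' Returns `(x - x_center) W (P'W)^{-1}` for each row, i.e. the latent
#' coordinates used by the robust reweighting and leverage diagnostics.
#'
#' @inheritParams predict.pls_model
#' @param x rows to project (defaults must be supplied by caller).
#' @return numeric matrix with `l` columns.
#' @export
pls_scores <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(object$x_center))
    stop_dim("x has ", ncol(x), " columns; model expects ",
             length(object$x_center))
  sweep(x, 2, object$x_center) %*% object$projection
}

#' Refit a PLS model under new observation weights
#'
#' Convenience wrapper shared by the robust estimators: replaces the
#' dataset's observation weights and calls [nipals_fit()]. Weights scale
#' rows by their square root after weighted centering, so zero weights
#' delete observations exactly.
#'
#' @inheritParams nipals_fit
#' @param weights nonnegative weights of length `n`, not all zero.
#' @return A `"pls_model"`.
#' @export
weighted_refit <- function(data, weights, l, tol = 1e-4, max_iter = 500) {
  data <- as_dataset(data)
  d2 <- regression_dataset(data$x, data$y, obs_weights = weights)
  nipals_fit(d2, l = l, tol = tol, max_iter = max_iter)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", x$l, "component(s),", length(x$coef), "predictor(s)\n")
  cat("  y center:", format(x$y_center, digits = 4), "\n")
  invisible(x)
}
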