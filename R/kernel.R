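#' Kernel specification
#'
#' @param family `"gaussian"` (default) or `"linear"`.
#' @param sigma2 positive Gaussian bandwidth (denominator of the squared
#'   distance), or `"auto"` to resolve it from the training predictors via
#'   [resolve_sigma2()].
#' @return list of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("gaussian", "linear"), sigma2 = "auto") {
  family <- match.arg(family)
  if (family == "gaussian" && !identical(sigma2, "auto")) {
    sigma2 <- as.numeric(sigma2)
    if (!is.finite(sigma2) || sigma2 <= 0)
      stop_dim("sigma2 must be positive (or \"auto\")")
  }
  structure(list(family = family, sigma2 = sigma2), class = "kernel_spec")
}

#' Gaussian kernel Gram matrix between two row sets
#'
#' `K_ij = exp(-||a_i - b_j||^2 / sigma2)`.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @param sigma2 positive bandwidth.
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
gaussian_kernel <- function(A, B, sigma2) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop_dim("A and B must have matching columns")
  if (!is.finite(sigma2) || sigma2 <= 0) stop_dim("sigma2 must be positive")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

eval_kernel <- function(A, B, spec) {
  switch(spec$family,
         gaussian = gaussian_kernel(A, B, spec$sigma2),
         linear = tcrossprod(as.matrix(A), as.matrix(B)))
}

#' Default Gaussian bandwidth from the training predictors
#'
#' `sigma2` is the total (non-robust) variance of the training matrix: the
#' sum over columns of the per-column sample variances, i.e. `m` times the
#' mean column variance. For a single predictor this is simply its sample
#' variance.
#'
#' @param X training predictor matrix, `n >= 2` rows.
#' @return positive scalar.
#' @export
resolve_sigma2 <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_dim("need at least 2 rows")
  s2 <- sum(apply(X, 2, var))
  if (!is.finite(s2) || s2 <= 0)
    stop_dim("training predictors have zero total variance")
  s2
}

resolve_spec <- function(spec, X) {
  if (spec$family == "gaussian" && identical(spec$sigma2, "auto"))
    spec$sigma2 <- resolve_sigma2(X)
  spec
}

#' Double-center a training Gram matrix
#'
#' Centers the implicit feature map at the (weighted) mean of the training
#' features and, when weights are supplied, scales feature rows by
#' `sqrt(w_i)`: `K_c = S (K - 1 c' - c 1' + g 1 1') S` with
#' `c = K w / sum(w)`, `g = w'Kw / sum(w)^2`, `S = diag(sqrt(w))`. With
#' unit weights this is the usual `(I - 11'/n) K (I - 11'/n)`. The
#' returned statistics are what [center_kernel_test()] needs to center a
#' test kernel block against the same training features.
#'
#' @param K symmetric `n x n` training Gram matrix.
#' @param w optional nonnegative observation weights (default all 1).
#' @return list with `Kc` (centered, weight-scaled Gram matrix) and
#'   `stats` (`col_means`, `grand_mean`, `w`, `wn`, `sqrt_w`).
#' @export
center_kernel <- function(K, w = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop_dim("K must be square")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(w < 0) || all(w == 0))
    stop_dim("w must be nonnegative, length n, not all zero")
  wn <- w / sum(w)
  cm <- as.vector(K %*% wn)
  g <- sum(wn * cm)
  sw <- sqrt(w)
  Kc <- (K - outer(cm, rep(1, n)) - outer(rep(1, n), cm) + g)
  Kc <- Kc * tcrossprod(sw, sw)
  list(Kc = Kc,
       stats = list(col_means = cm, grand_mean = g, w = w, wn = wn,
                    sqrt_w = sw))
}

#' Center a test kernel block against training centering statistics
#'
#' Applies the matching transform for test rows: subtract the test rows'
#' (weighted) mean kernel value against the training set and the training
#' column means, add back the grand mean, and scale columns by
#' `sqrt(w_j)`.
#'
#' @param Kv `n_v x n` kernel block of test rows against training rows.
#' @param stats the `stats` element returned by [center_kernel()].
#' @return centered `n_v x n` matrix.
#' @export
center_kernel_test <- function(Kv, stats) {
  Kv <- as.matrix(Kv)
  n <- length(stats$col_means)
  if (ncol(Kv) != n) stop_dim("Kv must have one column per training row")
  rowm <- as.vector(Kv %*% stats$wn)
  A <- Kv - outer(rowm, rep(1, n)) -
    outer(rep(1, nrow(Kv)), stats$col_means) + stats$grand_mean
  sweep(A, 2, stats$sqrt_w, "*")
}

#' Kernel NIPALS for a univariate response
#'
#' Extracts `l` components from a centered Gram matrix: the latent score
#' `v = K u / ||K u||` (unit norm), the y-side score is updated from the
#' projection of `y` on `v`, and `K` and `y` are deflated with
#' `(I - v v')` between components. With a univariate response the inner
#' loop converges in one pass; the stated tolerance guards degenerate
#' input.
#'
#' @param Kc centered symmetric Gram matrix.
#' @param yc centered response vector.
#' @param l number of components, `l <= n - 1`.
#' @param tol inner-loop tolerance on the normalized y-score change
#'   (default 1e-4).
#' @param max_iter inner-loop cap.
#' @return list with `V` (`n x l`, orthonormal columns), `U` (`n x l`
#'   normalized y-scores), `dual_coef` (`alpha` with
#'   `yhat = Kc alpha`), `proj` (`U (V'KU)^{-1}`, maps centered kernel
#'   rows to scores), `l` (components actually extracted).
#' @export
kernel_nipals <- function(Kc, yc, l, tol = 1e-4, max_iter = 500) {
  Kc <- as.matrix(Kc)
  n <- nrow(Kc)
  if (length(yc) != n) stop_dim("length(yc) must equal nrow(Kc)")
  if (l < 1 || l > n - 1) stop_dim("l must be in [1, n - 1]")
  V <- matrix(0, n, l); U <- matrix(0, n, l)
  Kg <- Kc; yg <- yc
  l_used <- 0L
  for (g in seq_len(l)) {
    if (sum(yg^2) < 1e-24) break
    u <- yg / sqrt(sum(yg^2))
    v <- NULL
    for (it in seq_len(max_iter)) {
      wv <- as.vector(Kg %*% u)
      nv <- sqrt(sum(wv^2))
      if (nv < 1e-12) { v <- NULL; break }
      v <- wv / nv
      cg <- sum(yg * v)                    # v'v = 1
      u_new <- yg * cg
      nu <- sqrt(sum(u_new^2))
      if (nu < 1e-24) { v <- NULL; break }
      u_new <- u_new / nu
      if (max(abs(u_new - u)) < tol) { u <- u_new; break }
      u <- u_new
    }
    if (is.null(v)) break
    V[, g] <- v; U[, g] <- u
    Kv <- as.vector(Kg %*% v)
    Kg <- Kg - tcrossprod(v, Kv) - tcrossprod(Kv, v) +
      sum(v * Kv) * tcrossprod(v, v)
    yg <- yg - v * sum(v * yg)
    l_used <- g
  }
  if (l_used == 0L) stop_dim("no kernel component could be extracted")
  if (l_used < l)
    warning("extracted ", l_used, " of ", l, " requested kernel components")
  V <- V[, seq_len(l_used), drop = FALSE]
  U <- U[, seq_len(l_used), drop = FALSE]
  A <- crossprod(V, Kc %*% U)              # l x l
  proj <- U %*% solve(A)
  alpha <- as.vector(proj %*% crossprod(V, yc))
  list(V = V, U = U, dual_coef = alpha, proj = proj, l = l_used)
}

# Shared constructor for (possibly weighted) kernel PLS fits. Weights act
# as sqrt(w) scalings of the centered feature rows, so 0/1 weights are
# exactly equivalent to deleting rows before fitting.
kernel_pls_engine <- function(data, l, spec, w = NULL, tol = 1e-4,
                              y_shift = 0, y_scale = 1) {
  data <- as_dataset(data)
  n <- data$n
  if (is.null(w)) w <- data$obs_weights
  spec <- resolve_spec(spec, data$x)
  K <- eval_kernel(data$x, data$x, spec)
  cen <- center_kernel(K, w)
  wn <- cen$stats$wn
  ys <- (data$y - y_shift) / y_scale
  y_center <- sum(wn * ys)
  yc <- (ys - y_center) * cen$stats$sqrt_w
  n_eff <- sum(w > 0)
  if (l > n_eff - 1)
    stop_dim("l = ", l, " exceeds n_eff - 1 = ", n_eff - 1)
  km <- kernel_nipals(cen$Kc, yc, l = l, tol = tol)
  structure(list(spec = spec, x_train = data$x, center_stats = cen$stats,
                 Kc = cen$Kc, V = km$V, U = km$U, dual_coef = km$dual_coef,
                 proj = km$proj, y_center = y_center, y_shift = y_shift,
                 y_scale = y_scale, yc = yc, obs_weights = w, l = km$l),
            class = "kpls_model")
}

#' Kernel PLS1 regression
#'
#' Maps the predictors into a reproducing kernel Hilbert space through the
#' Gaussian (or linear) kernel, double-centers the Gram matrix and runs
#' kernel NIPALS. Prediction uses the dual form
#' `yhat_v = Kv U (V' K U)^{-1} V' y` with the centered test kernel block.
#'
#' @param data a [regression_dataset()].
#' @param l number of latent components.
#' @param spec a [kernel_spec()]; the default resolves the Gaussian
#'   bandwidth as the total variance of the training predictors.
#' @param tol kernel NIPALS tolerance.
#' @return Object of class `"kpls_model"` (see [kernel_nipals()]; also
#'   carries the training rows and centering statistics needed at
#'   prediction time).
#' @export
kpls_fit <- function(data, l, spec = kernel_spec("gaussian", "auto"),
                     tol = 1e-4) {
  kernel_pls_engine(data, l = l, spec = spec, w = NULL, tol = tol)
}

#' Predict from a kernel PLS model
#'
#' @param object a `"kpls_model"`.
#' @param newdata matrix of new rows (vector taken as a single row).
#' @param ... unused.
#' @return numeric predictions on the original response scale.
#' @export
predict.kpls_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_train))
    stop_dim("newdata has ", ncol(newdata), " columns; model expects ",
             ncol(object$x_train))
  Kv <- eval_kernel(newdata, object$x_train, object$spec)
  Kvc <- center_kernel_test(Kv, object$center_stats)
  yhat <- as.vector(Kvc %*% object$dual_coef) + object$y_center
  yhat * object$y_scale + object$y_shift
}

#' Latent kernel scores of (new) observations
#'
#' Projects rows onto the kernel PLS score space,
#' `V_new = Kv_c U (V' K U)^{-1}`; on the training rows of an unweighted
#' fit this reproduces the orthonormal training scores.
#'
#' @inheritParams predict.kpls_model
#' @param x rows to project.
#' @return matrix with `l` columns.
#' @export
kpls_scores <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  Kv <- eval_kernel(as.matrix(x), object$x_train, object$spec)
  Kvc <- center_kernel_test(Kv, object$center_stats)
  Kvc %*% object$proj
}

#' @export
print.kpls_model <- function(x, ...) {
  cat("Kernel PLS model:", x$l, "component(s);", x$spec$family,
      "kernel", if (x$spec$family == "gaussian")
        paste0("(sigma2 = ", format(x$spec$sigma2, digits = 4), ")") else "",
      "\n")
  invisible(x)
}
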