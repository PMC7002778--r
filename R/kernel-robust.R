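#' Kernel partial robust M-regression (KPRM)
#'
#' Iteratively reweighted kernel PLS: the PRM generalized weights
#' `w_i = w_i^r * w_i^x` (MAD-standardized residual weights times
#' L1-median leverage weights on the kernel score rows) enter the kernel
#' fit as `sqrt(w_i)` scalings of the centered feature rows, i.e. the
#' weighted Gram matrix `Omega K Omega` with `Omega = diag(sqrt(w))` and
#' weight-aware centering.
#'
#' @param data a [regression_dataset()].
#' @param config a [robust_pls_config()].
#' @param spec a [kernel_spec()]; the Gaussian bandwidth is resolved once
#'   from the full training predictors.
#' @return Object of class `"kernel_robust"`: `base` (final
#'   `"kpls_model"`), `omega` (final generalized weights), `state`
#'   (`"irls_state"`), `method = "kprm"`.
#' @export
kprm_fit <- function(data, config = robust_pls_config(),
                     spec = kernel_spec("gaussian", "auto")) {
  data <- as_dataset(data)
  n <- data$n
  spec <- resolve_spec(spec, data$x)
  w <- rep(1, n)
  fit <- NULL; yhat_old <- NULL
  best <- NULL; best_obj <- Inf
  converged <- FALSE
  f <- numeric(n); s_hat <- NA_real_; it_used <- 0L
  for (it in seq_len(config$max_irls_iter)) {
    fit <- kernel_pls_engine(data, l = config$l, spec = spec, w = w)
    yhat <- predict(fit, data$x)
    f <- data$y - yhat
    s_hat <- mad_scale(f)
    if (!is.finite(s_hat) || s_hat <= 0) { converged <- TRUE; it_used <- it; break }
    wr <- residual_weights(f, s_hat, config$residual_weight)
    Vall <- kpls_scores(fit, data$x)
    wx <- tryCatch(as.numeric(score_weights(Vall, config$score_weight)),
                   error = function(e) rep(1, n))
    w_new <- pmax(wr * wx, 1e-6)
    obj <- sum(w_new * f^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(fit = fit, w = w_new, f = f, s = s_hat, it = it)
    }
    it_used <- it
    if (!is.null(yhat_old)) {
      rel <- sqrt(sum((yhat - yhat_old)^2)) /
        max(sqrt(sum(yhat_old^2)), .Machine$double.eps)
      if (rel < config$irls_tol) { converged <- TRUE; w <- w_new; break }
    }
    yhat_old <- yhat
    w <- w_new
  }
  if (is.null(best)) best <- list(fit = fit, w = w, f = f, s = s_hat,
                                  it = it_used)
  state <- structure(list(iteration = best$it, residuals = best$f,
                          scale = best$s, weights = best$w,
                          objective = best_obj, converged = converged),
                     class = "irls_state")
  structure(list(base = best$fit, omega = best$w, state = state,
                 diagnostics = state, method = "kprm"),
            class = "kernel_robust")
}

#' Kernel partial diagnostic robust potential regression (KPDRGP)
#'
#' The proposed robust kernel calibration method. The response is
#' normalized to zero mean and unit variance (inverted at prediction);
#' the Gaussian bandwidth is the total variance of the training
#' predictors. Each cycle: (1) fit kernel PLS on the weighted Gram matrix
#' (0/1 weights, weight-aware centering); (2) run the DRGP procedure --
#' MVE robust Mahalanobis screening with the `median + 3 MAD` cut-off,
#' then group-deleted generalized potentials with the put-back rule -- on
#' the diagnostic score rows of the retained observations (the leading
#' y-side latent scores together with the fit residual, see `l_diag`);
#' (3) set the weight of confirmed outlier / high-leverage rows to 0 and
#' refit. Deleted rows stay deleted (monotone flag set); cycling stops
#' when no new row is flagged or after `max_cycles` (default a single
#' diagnose-and-refit pass, which keeps the screen from chasing
#' residual noise once the gross outliers are removed).
#'
#' @param data a [regression_dataset()].
#' @param config a [robust_pls_config()] (`l`, `seed` used).
#' @param spec a [kernel_spec()].
#' @param c potential cut-off constant (default 3).
#' @param mve_trials MVE resampling trials (default 500).
#' @param max_cycles cap on diagnose-refit cycles (default 10).
#' @param l_diag number of leading latent components whose y-side scores
#'   enter the diagnostic input space alongside the fit residual
#'   (default 1; capped at `l`). Vertical response outliers surface in
#'   the y-side scores and residuals, whereas the x-side kernel scores
#'   are functions of the predictors alone and cannot reveal them;
#'   keeping the screen low-dimensional also keeps the MVE well
#'   conditioned at calibration-set sizes of a few dozen.
#' @return Object of class `"kernel_robust"`: `base` (final
#'   `"kpls_model"`), `omega` (0/1 weights), `diagnostics` (last cycle's
#'   `"drgp_result"` mapped to original row indices), `flags` (logical,
#'   original indexing), `n_cycles`, `method = "kpdrgp"`.
#' @export
kpdrgp_fit <- function(data, config = robust_pls_config(),
                       spec = kernel_spec("gaussian", "auto"), c = 3,
                       mve_trials = 500, max_cycles = 1, l_diag = 1) {
  data <- as_dataset(data)
  n <- data$n
  spec <- resolve_spec(spec, data$x)
  y_shift <- mean(data$y)
  y_scale <- sd(data$y)
  if (!is.finite(y_scale) || y_scale <= 0)
    stop_dim("response has zero variance")
  seed0 <- config$seed %||% 1L
  w <- rep(1, n)
  fit <- NULL; dr <- NULL
  cycles <- 0L
  needs_refit <- FALSE
  for (cy in seq_len(max_cycles)) {
    active <- which(w > 0)
    if (length(active) < config$l + 2)
      stop_dim("fewer than l + 2 observations survive; ",
               "loosen the cut-off or reduce l")
    fit <- kernel_pls_engine(data, l = config$l, spec = spec, w = w,
                             y_shift = y_shift, y_scale = y_scale)
    needs_refit <- FALSE
    cycles <- cy
    ld <- min(l_diag, fit$l)
    e_act <- (data$y - predict(fit, data$x))[active]
    V_act <- cbind(fit$U[active, seq_len(ld), drop = FALSE], e_act)
    dr_try <- tryCatch(
      drgp_run(V_act, c = c, mve_trials = mve_trials,
               seed = (seed0 + cy - 1L) %% .Machine$integer.max),
      error = function(e) NULL)
    if (is.null(dr_try)) break
    dr <- dr_try
    new_flags <- active[dr$final_flags]
    if (length(new_flags) == 0) break
    if (length(active) - length(new_flags) < config$l + 2) {
      # keep the fit estimable: drop only the most extreme rows
      keep_n <- length(active) - (config$l + 2)
      if (keep_n <= 0) break
      new_flags <- new_flags[order(dr$rmd2[dr$final_flags],
                                   decreasing = TRUE)][seq_len(keep_n)]
    }
    w[new_flags] <- 0
    needs_refit <- TRUE
  }
  if (needs_refit)   # deletions from the last diagnostic pass
    fit <- kernel_pls_engine(data, l = config$l, spec = spec, w = w,
                             y_shift = y_shift, y_scale = y_scale)
  flags <- w == 0
  if (!is.null(dr)) dr$flagged_rows <- which(flags)
  structure(list(base = fit, omega = w, diagnostics = dr,
                 flags = flags, n_cycles = cycles, method = "kpdrgp"),
            class = "kernel_robust")
}

#' @export
predict.kernel_robust <- function(object, newdata, ...) {
  predict(object$base, newdata, ...)
}

#' @export
print.kernel_robust <- function(x, ...) {
  cat("Robust kernel PLS fit (", toupper(x$method), "): ", x$base$l,
      " component(s)\n", sep = "")
  if (x$method == "kpdrgp")
    cat("  flagged rows:", paste(which(x$flags), collapse = ", "),
        if (!any(x$flags)) "none", "\n")
  invisible(x)
}
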