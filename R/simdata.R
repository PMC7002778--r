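#' Configuration of the contaminated sine calibration study
#'
#' The study draws training abscissae uniformly on `x_range`, evaluates
#' `f(x) = sin(-0.75 x)`, adds Gaussian noise, and shifts a fixed set of
#' training samples vertically to create gross response outliers. Defaults
#' reproduce the study conditions: 41 training samples on [0, 10], noise
#' SD 0.05, outliers at sample numbers 10, 12, 18, 19, 28, 33, 36, and a
#' shift magnitude drawn from Uniform(1, 2) (the sine has amplitude 1, so
#' shifts of 1-2 response units are unambiguous vertical outliers) with
#' sign pushing away from the curve.
#'
#' @param n_train training samples (default 41).
#' @param n_test test grid size (default 101).
#' @param x_range length-2 numeric interval (default c(0, 10)).
#' @param noise_sd response noise SD (> 0, default 0.05).
#' @param outlier_indices 1-based distinct indices within `[1, n_train]`
#'   (samples ordered by increasing x).
#' @param outlier_shift either `"uniform"` (draw magnitude from
#'   Uniform(1, 2) per outlier) or a fixed positive magnitude.
#' @param seed integer seed.
#' @return list of class `"sine_sim_config"`.
#' @export
sine_sim_config <- function(n_train = 41, n_test = 101, x_range = c(0, 10),
                            noise_sd = 0.05,
                            outlier_indices = c(10, 12, 18, 19, 28, 33, 36),
                            outlier_shift = "uniform", seed = 1) {
  if (length(x_range) != 2 || x_range[1] >= x_range[2])
    stop_dim("x_range must be an increasing interval")
  if (noise_sd <= 0) stop_dim("noise_sd must be > 0")
  outlier_indices <- as.integer(outlier_indices)
  if (anyDuplicated(outlier_indices))
    stop_dim("outlier_indices must be distinct")
  if (length(outlier_indices) &&
      (min(outlier_indices) < 1 || max(outlier_indices) > n_train))
    stop_dim("outlier_indices must lie within [1, n_train]")
  if (!identical(outlier_shift, "uniform")) {
    outlier_shift <- as.numeric(outlier_shift)
    if (outlier_shift <= 0) stop_dim("outlier_shift must be positive")
  }
  structure(list(n_train = n_train, n_test = n_test, x_range = x_range,
                 noise_sd = noise_sd, outlier_indices = outlier_indices,
                 outlier_shift = outlier_shift, seed = seed),
            class = "sine_sim_config")
}

sine_truth <- function(x) sin(-0.75 * x)

new_sim_dataset <- function(x, y, flags, meta) {
  structure(list(x = as.matrix(x), y = as.numeric(y),
                 truth_flags = as.logical(flags), meta = meta),
            class = c("simulated_dataset"))
}

#' Simulate the contaminated sine training set
#'
#' Draws `n_train` abscissae iid Uniform on `x_range` (sorted increasing,
#' so outlier sample numbers refer to position along the curve), sets
#' `y = sin(-0.75 x) + e`, `e ~ N(0, noise_sd^2)`, then shifts the
#' configured samples vertically away from the curve.
#'
#' @param config a [sine_sim_config()].
#' @return list of class `"simulated_dataset"`: `x` (n x 1 matrix), `y`,
#'   `truth_flags` (injected outliers), `y_clean` (pre-contamination
#'   response), `meta` (the config).
#' @export
simulate_sine <- function(config = sine_sim_config()) {
  stopifnot(inherits(config, "sine_sim_config"))
  local_seed(config$seed, {
    x <- sort(runif(config$n_train, config$x_range[1], config$x_range[2]))
    eps <- rnorm(config$n_train, 0, config$noise_sd)
    y <- sine_truth(x) + eps
    y_clean <- y
    flags <- rep(FALSE, config$n_train)
    k <- length(config$outlier_indices)
    if (k > 0) {
      mag <- if (identical(config$outlier_shift, "uniform"))
        runif(k, 1, 2) else rep(config$outlier_shift, k)
      sgn <- ifelse(eps[config$outlier_indices] >= 0, 1, -1)
      y[config$outlier_indices] <- y[config$outlier_indices] + sgn * mag
      flags[config$outlier_indices] <- TRUE
    }
    out <- new_sim_dataset(matrix(x, ncol = 1,
                                  dimnames = list(NULL, "x_1")),
                           y, flags, config)
    out$y_clean <- y_clean
    out
  })
}

#' Simulate the sine test grid
#'
#' `n_test` points equally spaced over `x_range` with the same noise
#' model and no contamination. The noiseless truth is returned alongside
#' for diagnostics.
#'
#' @param config a [sine_sim_config()].
#' @param seed optional seed for the test noise (default `config$seed + 1`).
#' @return a `"simulated_dataset"` with extra element `y_clean`.
#' @export
simulate_sine_test <- function(config = sine_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sine_sim_config"))
  seed <- seed %||% (config$seed + 1L)
  local_seed(seed, {
    x <- seq(config$x_range[1], config$x_range[2],
             length.out = config$n_test)
    y_clean <- sine_truth(x)
    y <- y_clean + rnorm(config$n_test, 0, config$noise_sd)
    out <- new_sim_dataset(matrix(x, ncol = 1,
                                  dimnames = list(NULL, "x_1")),
                           y, rep(FALSE, config$n_test), config)
    out$y_clean <- y_clean
    out
  })
}

#' Simulate NIR-like overlapping-peak spectra with a nonlinear link
#'
#' Emulates the shape of a fruit-mesocarp NIR calibration set: each
#' spectrum is a sum of `n_peaks` Gaussian absorption bands whose
#' amplitudes depend on a latent concentration `y` (a bounded percentage,
#' Uniform(40, 80)) through a saturating link blended with a linear one by
#' `nonlinearity`, plus per-peak amplitude jitter, multiplicative scatter
#' `(1 + N(0, scatter_sd^2))` and an additive smooth baseline scaled by
#' `N(0, baseline_sd^2)`. A `contamination_rate` fraction of rows is
#' corrupted (half response outliers, half leverage rows with inflated
#' spectra) and flagged.
#'
#' @param n,m samples and wavelengths (defaults 960 and 489, the scale of
#'   an oil-palm mesocarp NIR study).
#' @param n_peaks number of absorption bands (default 6).
#' @param scatter_sd multiplicative scatter SD (default 0.02).
#' @param baseline_sd baseline scale SD (default 0.05).
#' @param nonlinearity blend in [0, 1] between a linear and a saturating
#'   concentration link (default 0.5).
#' @param contamination_rate fraction in [0, 0.5) of corrupted rows
#'   (default 0).
#' @param seed integer seed.
#' @return a `"simulated_dataset"` (`x` is `n x m`, columns `x_1..x_m`).
#' @export
simulate_nir <- function(n = 960, m = 489, n_peaks = 6, scatter_sd = 0.02,
                         baseline_sd = 0.05, nonlinearity = 0.5,
                         contamination_rate = 0, seed = 1) {
  stopifnot(n >= 1, m >= 1, n_peaks >= 1,
            contamination_rate >= 0, contamination_rate < 0.5)
  local_seed(seed, {
    wl <- seq(0, 1, length.out = m)
    centers <- seq(0.1, 0.9, length.out = n_peaks)
    widths <- runif(n_peaks, 0.03, 0.08)
    peaks <- sapply(seq_len(n_peaks), function(k)
      exp(-(wl - centers[k])^2 / (2 * widths[k]^2)))   # m x n_peaks
    alpha <- runif(n_peaks, 0.2, 0.5)
    beta <- runif(n_peaks, 0.5, 1.5)
    baseline_shape <- 0.5 + wl - 0.6 * wl^2

    y <- runif(n, 40, 80)
    yt <- y / 100
    g <- (1 - nonlinearity) * yt + nonlinearity * (1 - exp(-3 * yt))
    amp <- outer(g, beta) + matrix(alpha, n, n_peaks, byrow = TRUE) +
      matrix(rnorm(n * n_peaks, 0, 0.02), n, n_peaks)
    X <- amp %*% t(peaks)
    if (baseline_sd > 0)
      X <- X + tcrossprod(rnorm(n, 0, baseline_sd), baseline_shape)
    if (scatter_sd > 0)
      X <- X * (1 + rnorm(n, 0, scatter_sd))

    flags <- rep(FALSE, n)
    n_bad <- floor(contamination_rate * n)
    if (n_bad > 0) {
      bad <- sample.int(n, n_bad)
      flags[bad] <- TRUE
      half <- length(bad) %/% 2
      y_bad <- bad[seq_len(max(half, 1))]
      x_bad <- setdiff(bad, y_bad)
      y[y_bad] <- y[y_bad] +
        sample(c(-1, 1), length(y_bad), replace = TRUE) * 6 * sd(y)
      if (length(x_bad))
        X[x_bad, ] <- X[x_bad, , drop = FALSE] * 3
    }
    colnames(X) <- paste0("x_", seq_len(m))
    new_sim_dataset(X, y, flags,
                    list(n = n, m = m, n_peaks = n_peaks,
                         scatter_sd = scatter_sd, baseline_sd = baseline_sd,
                         nonlinearity = nonlinearity,
                         contamination_rate = contamination_rate,
                         seed = seed))
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$x), "x", ncol(x$x), "predictors;",
      sum(x$truth_flags), "contaminated row(s)\n")
  invisible(x)
}

#' Coerce a simulated dataset to a calibration dataset
#'
#' @param sim a `"simulated_dataset"`.
#' @return a [regression_dataset()].
#' @export
as_regression_dataset <- function(sim) {
  regression_dataset(sim$x, sim$y)
}
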