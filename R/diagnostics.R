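#' Minimum volume ellipsoid location and shape by resampling
#'
#' Classical subsampling MVE: for each trial an elemental subset of
#' `l + 1` rows gives a mean and covariance; the candidate ellipsoid is
#' inflated to cover `h = floor((n + l + 1) / 2)` points and the
#' minimum-volume candidate wins. The final shape is rescaled by
#' `median(d^2) / qchisq(0.5, l)` for consistency at the normal model.
#'
#' @param V numeric matrix of points (`n x l`), `n > l + 1`.
#' @param n_trials number of elemental subsets (default 500).
#' @param seed integer seed; the estimate is reproducible bitwise for a
#'   given seed.
#' @return Object of class `"mve_estimate"`: `location` (`l`-vector),
#'   `shape` (`l x l` SPD matrix), `best_volume`, `n_trials`, `seed`, `h`.
#' @export
mve_fit <- function(V, n_trials = 500, seed) {
  V <- as.matrix(V)
  n <- nrow(V); l <- ncol(V)
  if (n <= l + 1) stop_dim("need n > l + 1 rows for the MVE")
  h <- floor((n + l + 1) / 2)
  local_seed(seed, {
    best <- NULL; best_logvol <- Inf
    for (t in seq_len(n_trials)) {
      idx <- sample.int(n, l + 1)
      # grow degenerate subsets until the covariance is nonsingular
      repeat {
        S <- V[idx, , drop = FALSE]
        m <- colMeans(S)
        C <- cov(S)
        ch <- tryCatch(chol(C), error = function(e) NULL)
        if (!is.null(ch) || length(idx) >= h) break
        idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
      }
      if (is.null(ch)) next
      d2 <- mahalanobis(V, m, C)
      mj <- sort(d2, partial = h)[h]
      if (mj <= 0) next
      # log volume of the covering ellipsoid: 0.5 log det(C) + (l/2) log mj
      logvol <- sum(log(diag(ch))) + (l / 2) * log(mj)
      if (logvol < best_logvol) {
        best_logvol <- logvol
        best <- list(m = m, C = C * mj)
      }
    }
    if (is.null(best))
      stop_dim("all elemental subsets were singular; MVE not estimable")
    d2 <- mahalanobis(V, best$m, best$C)
    corr <- median(d2) / qchisq(0.5, df = l)
    shape <- best$C * corr
    structure(list(location = best$m, shape = shape,
                   best_volume = exp(best_logvol), n_trials = n_trials,
                   seed = seed, h = h),
              class = "mve_estimate")
  })
}

#' Squared robust Mahalanobis distances against an MVE estimate
#'
#' @param V points (`n x l`).
#' @param est an [mve_fit()] result (or any list with `location`, `shape`).
#' @return nonnegative numeric vector `RM^2_i`.
#' @export
robust_mahalanobis <- function(V, est) {
  V <- as.matrix(V)
  if (ncol(V) != length(est$location))
    stop_dim("dimension mismatch between V and the MVE estimate")
  d2 <- tryCatch(mahalanobis(V, est$location, est$shape),
                 error = function(e) {
                   # ill-conditioned shape: symmetric eigen pseudo-solve
                   eg <- eigen(est$shape, symmetric = TRUE)
                   pos <- eg$values > max(eg$values) * 1e-12
                   Xi <- sweep(V, 2, est$location)
                   Z <- Xi %*% eg$vectors[, pos, drop = FALSE]
                   rowSums(sweep(Z^2, 2, eg$values[pos], "/"))
                 })
  pmax(d2, 0)
}

#' Cut-off for robust squared distances
#'
#' `median(RM^2) + 3 * MAD(RM^2)` with the raw (unscaled) MAD.
#'
#' @param rmd2 numeric vector of squared robust distances, length >= 3.
#' @return scalar cut-off.
#' @export
rmd_cutoff <- function(rmd2) {
  if (length(rmd2) < 3) stop_dim("need at least 3 distances")
  median(rmd2) + 3 * mad_scale(rmd2, constant = 1)
}

#' Group-deleted generalized potentials
#'
#' With suspect set `D` deleted and `R` the remaining rows, computes
#' `w_ii^(-D)`, the i-th diagonal of `V (V_R' V_R)^{-1} V'` for every row,
#' and returns the generalized potential: `w / (1 - w)` for retained rows,
#' `w` itself for deleted rows.
#'
#' @param V score matrix (`n x l`).
#' @param D integer indices of the deleted (suspect) set; may be empty.
#' @return nonnegative potentials `p_ii*` with attribute `"w_del"` holding
#'   the deleted-hat diagonals.
#' @export
generalized_potentials <- function(V, D = integer(0)) {
  V <- as.matrix(V)
  n <- nrow(V); l <- ncol(V)
  D <- sort(unique(as.integer(D)))
  if (length(D) && (min(D) < 1 || max(D) > n))
    stop_dim("D contains out-of-range indices")
  R <- setdiff(seq_len(n), D)
  if (length(R) <= l)
    stop_dim("remaining set has <= l rows; shrink the suspect set D")
  VR <- V[R, , drop = FALSE]
  M <- tryCatch(solve(crossprod(VR)),
                error = function(e)
                  stop_dim("V_R'V_R is singular; shrink the suspect set D"))
  w <- rowSums((V %*% M) * V)
  p <- w
  in_R <- seq_len(n) %in% R
  denom <- 1 - w[in_R]
  denom[denom < .Machine$double.eps] <- .Machine$double.eps
  p[in_R] <- w[in_R] / denom
  p <- pmax(p, 0)
  attr(p, "w_del") <- w
  p
}

#' Cut-off for generalized potentials
#'
#' `median(p) + c * MAD(p)` where here `MAD(p) = median|p - median(p)| /
#' 0.6475`, the scaling printed with the potential rule (slightly different
#' from the usual 1/1.4826 = 0.6745 inverse factor; kept exactly as
#' specified).
#'
#' @param p potentials.
#' @param c constant, conventionally 2 or 3 (default 3).
#' @return scalar cut-off.
#' @export
potential_cutoff <- function(p, c = 3) {
  med <- median(p)
  med + c * (median(abs(p - med)) / 0.6475)
}

#' Diagnostic robust generalized potentials (DRGP) on a score matrix
#'
#' Two steps. Step 1 screens suspects by MVE-based robust Mahalanobis
#' distance exceeding `median + 3 MAD`. Step 2 confirms them with
#' group-deleted generalized potentials: while any suspect's potential is
#' at or below the potential cut-off, the suspect with the smallest
#' potential is put back into the retained set and the potentials are
#' recomputed. Rows still suspect at the end are flagged and receive
#' weight 0; all others weight 1.
#'
#' @param V score matrix (`n x l`), `n > l + 1`.
#' @param c potential cut-off constant (default 3).
#' @param mve_trials MVE resampling trials (default 500).
#' @param seed integer seed for the MVE subsampling.
#' @return Object of class `"drgp_result"`: `rmd2`, `rmd_cutoff`,
#'   `suspects` (initial set), `potentials` (at the final configuration),
#'   `potential_cutoff`, `final_flags` (logical), `obs_weights` (0/1),
#'   `mve` (the [mve_fit()] estimate).
#' @export
drgp_run <- function(V, c = 3, mve_trials = 500, seed) {
  V <- as.matrix(V)
  n <- nrow(V); l <- ncol(V)
  est <- mve_fit(V, n_trials = mve_trials, seed = seed)
  rmd2 <- robust_mahalanobis(V, est)
  cut1 <- rmd_cutoff(rmd2)
  D0 <- which(rmd2 > cut1)
  # keep the deleted-set small enough for V_R'V_R to stay invertible
  max_d <- n - l - 2
  if (length(D0) > max_d)
    D0 <- D0[order(rmd2[D0], decreasing = TRUE)][seq_len(max_d)]
  D <- sort(D0)
  p <- generalized_potentials(V, D)
  cut2 <- potential_cutoff(p, c = c)
  while (length(D) > 0) {
    below <- D[p[D] <= cut2]
    if (length(below) == 0) break
    put_back <- below[which.min(p[below])]
    D <- setdiff(D, put_back)
    p <- generalized_potentials(V, D)
    cut2 <- potential_cutoff(p, c = c)
  }
  flags <- seq_len(n) %in% D
  structure(list(rmd2 = rmd2, rmd_cutoff = cut1, suspects = sort(D0),
                 potentials = as.numeric(p), potential_cutoff = cut2,
                 final_flags = flags, obs_weights = as.numeric(!flags),
                 mve = est),
            class = "drgp_result")
}

#' Partial robust DRGP regression (PRDRGP)
#'
#' Fits a plain PLS1 model, runs the DRGP procedure on its latent score
#' matrix (the scores replace the raw predictors as the diagnostic input
#' space), and refits with the confirmed high-leverage rows deleted
#' (weight 0).
#'
#' @param data a [regression_dataset()].
#' @param config a [robust_pls_config()] (`l`, `seed` used).
#' @param c potential cut-off constant (default 3).
#' @param mve_trials MVE resampling trials (default 500).
#' @return list of class `"robust_pls"` with `model` (refit), `diagnostics`
#'   (a `"drgp_result"`), `state` (NULL), `method = "prdrgp"`.
#' @export
prdrgp_fit <- function(data, config = robust_pls_config(), c = 3,
                       mve_trials = 500) {
  data <- as_dataset(data)
  base <- nipals_fit(data, l = config$l)
  V <- unname(pls_scores(base, data$x))
  dr <- drgp_run(V, c = c, mve_trials = mve_trials,
                 seed = config$seed %||% 1L)
  model <- if (any(dr$final_flags))
    weighted_refit(data, dr$obs_weights, l = config$l) else base
  structure(list(model = model, diagnostics = dr, state = NULL,
                 method = "prdrgp"),
            class = "robust_pls")
}

#' @export
print.drgp_result <- function(x, ...) {
  cat("DRGP diagnostics:", sum(x$final_flags), "of", length(x$final_flags),
      "rows flagged (initial suspects:", length(x$suspects), ")\n")
  invisible(x)
}

#' @export
print.mve_estimate <- function(x, ...) {
  cat("MVE estimate in", length(x$location), "dimensions (", x$n_trials,
      "trials, covering", x$h, "points)\n")
  invisible(x)
}
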