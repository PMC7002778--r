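KPDRGP_METHODS <- c("pls", "prm", "prmm", "prgm6", "prdrgp",
                    "kpls", "kprm", "kpdrgp")

#' Fit any of the calibration methods through one interface
#'
#' Dispatches to the eight implemented estimators. Non-kernel methods
#' (`pls`, `prm`, `prmm`, `prgm6`, `prdrgp`) use `l` capped at
#' `min(n - 1, m)`; kernel methods (`kpls`, `kprm`, `kpdrgp`) use `l`
#' capped at `n - 1`. All returned objects support `predict(fit, x_new)`.
#'
#' @param data a [regression_dataset()] (or list with `x`, `y`).
#' @param method one of `"pls"`, `"prm"`, `"prmm"`, `"prgm6"`,
#'   `"prdrgp"`, `"kpls"`, `"kprm"`, `"kpdrgp"`.
#' @param l requested number of latent components (default 5; capped per
#'   method as above).
#' @param spec a [kernel_spec()] for the kernel methods.
#' @param config optional [robust_pls_config()]; built from `l` and
#'   `seed` when missing.
#' @param seed integer seed for subsampling steps (MVE).
#' @param ... passed to the underlying fit function.
#' @return the method's fit object.
#' @export
#' @examples
#' sim <- simulate_sine(sine_sim_config(seed = 7))
#' fit <- calibrate(as_regression_dataset(sim), "kpdrgp", l = 5, seed = 7)
#' which(fit$flags)
calibrate <- function(data, method = KPDRGP_METHODS, l = 5,
                      spec = kernel_spec("gaussian", "auto"),
                      config = NULL, seed = 1, ...) {
  method <- match.arg(method)
  data <- as_dataset(data)
  kernel_method <- method %in% c("kpls", "kprm", "kpdrgp")
  l_eff <- if (kernel_method) min(l, data$n - 1) else
    min(l, data$n - 1, data$m)
  if (is.null(config)) config <- robust_pls_config(l = l_eff, seed = seed)
  else config$l <- l_eff
  switch(method,
         pls = nipals_fit(data, l = l_eff),
         prm = prm_fit(data, config),
         prmm = prmm_fit(data, config),
         prgm6 = gm6_fit(data, config, ...),
         prdrgp = prdrgp_fit(data, config, ...),
         kpls = kpls_fit(data, l = l_eff, spec = spec, ...),
         kprm = kprm_fit(data, config, spec = spec, ...),
         kpdrgp = kpdrgp_fit(data, config, spec = spec, ...))
}

#' Benchmark all methods on replicated sine simulations
#'
#' For each replicate, simulates a contaminated training set and a test
#' grid from `config`, fits every requested method, and computes the
#' evaluation metrics on both sets. Kernel methods use `l_kernel`
#' components, non-kernel methods `l_linear` (the sine study has a single
#' predictor, so linear fits have one component).
#'
#' @param config a [sine_sim_config()]; its seed is combined with the
#'   replicate number.
#' @param methods subset of the eight method names (default all).
#' @param replicates number of seeded replicates (default 25).
#' @param seed integer base seed.
#' @param l_kernel components for kernel fits (default 5).
#' @param l_linear requested components for linear fits (default 5, capped
#'   by the predictor count).
#' @param mve_trials MVE trials for the diagnostic methods (default 500).
#' @param test_on `"noisy"` (default) or `"clean"` test responses.
#' @return list with `results` (long data.frame: replicate, method,
#'   dataset, metric columns, and for kpdrgp the count of true/flagged
#'   outliers) and `summary` (median-aggregated method x dataset table).
#' @export
run_sine_benchmark <- function(config = sine_sim_config(),
                               methods = KPDRGP_METHODS, replicates = 25,
                               seed = 1, l_kernel = 5, l_linear = 5,
                               mve_trials = 500,
                               test_on = c("noisy", "clean")) {
  methods <- match.arg(methods, KPDRGP_METHODS, several.ok = TRUE)
  test_on <- match.arg(test_on)
  rows <- list()
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- (seed + 7919L * r) %% 2147483647L
    train <- simulate_sine(cfg)
    test <- simulate_sine_test(cfg, seed = (cfg$seed + 104729L) %% 2147483647L)
    y_test <- if (test_on == "noisy") test$y else test$y_clean
    tdat <- as_regression_dataset(train)
    for (mth in methods) {
      l_req <- if (mth %in% c("kpls", "kprm", "kpdrgp")) l_kernel
               else l_linear
      fit <- tryCatch(
        calibrate(tdat, mth, l = l_req, seed = cfg$seed,
                  config = robust_pls_config(l = l_req, seed = cfg$seed)),
        error = function(e) {
          warning("replicate ", r, ", method ", mth, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      # training metrics gauge how well the fitted curve tracks the
      # uncontaminated training response (the injected gross outliers are
      # measurement errors, not values a calibration should reproduce)
      m_tr <- compute_metrics(train$y_clean, predict(fit, train$x),
                              dataset_label = "train")
      m_te <- compute_metrics(y_test, predict(fit, test$x),
                              dataset_label = "test")
      n_true <- NA_integer_; n_flag <- NA_integer_
      if (mth == "kpdrgp") {
        n_flag <- sum(fit$flags)
        n_true <- sum(fit$flags & train$truth_flags)
      } else if (mth == "prdrgp") {
        n_flag <- sum(fit$diagnostics$final_flags)
        n_true <- sum(fit$diagnostics$final_flags & train$truth_flags)
      }
      for (mr in list(m_tr, m_te)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, method = mth, dataset = mr$dataset_label,
          rmse = mr$rmse, r2 = mr$r2, rpd = mr$rpd, bias = mr$bias,
          se = mr$se, n_flagged = n_flag, n_true_flagged = n_true,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    results, list(results$method, results$dataset), drop = TRUE),
    function(d) data.frame(
      method = d$method[1], dataset = d$dataset[1],
      rmse = median(d$rmse), r2 = median(d$r2), rpd = median(d$rpd),
      bias = median(d$bias), se = median(d$se),
      n_flagged = median(d$n_flagged), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  summary <- summary[order(match(summary$method, KPDRGP_METHODS),
                           summary$dataset), ]
  list(results = results, summary = summary)
}
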