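#' True performance of the modelling procedure under a simulation setting
#'
#' Average performance obtained when the logistic model is fitted on a
#' fresh complete data set of size `n` and evaluated on a large independent
#' complete data set with the same underlying effect sizes. This is the
#' reference ("truth") against which strategy estimates are compared; it is
#' generally below the theoretical AUC in small samples because estimation
#' error shrinks the achievable performance.
#'
#' @param config a [sim_config()].
#' @param n_test size of the independent evaluation data sets.
#' @param n_replicates number of fit/evaluate replicates averaged.
#' @param measure measure label.
#' @param seed optional RNG seed.
#' @return The scalar true performance.
#' @export
true_performance <- function(config, n_test = 10000, n_replicates = 20,
                             measure = "auc", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_test >= 1000)
  cfg_test <- config
  cfg_test$n <- as.integer(n_test)
  base_cols <- if (config$p0 > 0) seq_len(config$p0) else NULL
  need_base <- measure %in% added_measures
  vals <- vapply(seq_len(n_replicates), function(r) {
    train <- generate_complete(config)
    test <- generate_complete(cfg_test)
    ext <- fit_logistic(train$X, train$y)
    if (is.null(ext)) return(NA_real_)
    p <- predict(ext, test$X)
    pb <- NULL
    if (need_base) {
      base <- fit_logistic(train$X[, base_cols, drop = FALSE], train$y)
      pb <- predict(base, test$X[, base_cols, drop = FALSE])
    }
    compute_measure(measure, test$y, p, pb, config$frac)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Bias, variance and mean squared error of per-replicate estimates
#'
#' @param estimates numeric vector of per-replicate performance estimates.
#' @param truth reference performance.
#' @return A list with `truth`, `bias` (mean minus truth), `variance`
#'   (sample variance), `mse` (mean squared deviation from truth) and
#'   `n_replicates`.
#' @export
summarize_bias_mse <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2) stop("at least 2 replicates are required")
  list(truth = truth,
       bias = mean(estimates) - truth,
       variance = stats::var(estimates),
       mse = mean((estimates - truth)^2),
       n_replicates = length(estimates))
}

#' Type-1 error / power of CI-based tests over a configuration grid
#'
#' For each configuration, simulates data sets, runs the given strategy with
#' its confidence interval, and reports the fraction of intervals lying
#' entirely above the null value (0.5 for AUC, 0 for added measures). Under
#' the null this fraction is the type-1 error; under an effect it is power.
#'
#' @param configs list of [sim_config()] objects.
#' @param spec a [strategy_spec()] with `ci` set.
#' @param n_sim simulated data sets per configuration.
#' @param seed RNG seed.
#' @return A data frame with one row per configuration: theoretical `auc`,
#'   `rejection` rate and `n_sim`.
#' @export
type1_power_experiment <- function(configs, spec, n_sim = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  null_value <- if (spec$measure %in% added_measures) 0 else 0.5
  rows <- lapply(configs, function(cfg) {
    rej <- vapply(seq_len(n_sim), function(s) {
      dat <- simulate_dataset(cfg, seed = NULL)
      rep <- run_strategy(dat, spec)
      as.numeric(rep$ci[1] > null_value)
    }, numeric(1))
    data.frame(auc = if (cfg$p0 > 0) cfg$auc0 + cfg$dauc else cfg$auc,
               rejection = mean(rej), n_sim = n_sim)
  })
  do.call(rbind, rows)
}

#' Variability of the 0.632+ estimate over resampling/imputation runs
#'
#' For each data set and each (B, M) grid point, the strategy is re-run
#' `n_runs` times with fresh resampling and imputation randomness; the
#' standard deviation of the 0.632+ estimate across runs is averaged over
#' the data sets. Because the B resample contributions are independent, the
#' SD is expected to scale as `1/sqrt(B)` (and analogously in M for the
#' imputation-first strategies).
#'
#' @param datasets list of `incomplete_data` objects.
#' @param spec a [strategy_spec()] (its B and M are overridden).
#' @param B_grid,M_grid integer grids.
#' @param n_runs repeated runs per grid point and data set.
#' @return A data frame with columns `B`, `M` and `sd`.
#' @export
variability_curve <- function(datasets, spec, B_grid = c(1, 4, 16),
                              M_grid = 1, n_runs = 10) {
  stopifnot(n_runs >= 2)
  grid <- expand.grid(B = B_grid, M = M_grid)
  grid$sd <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sds <- vapply(datasets, function(dat) {
      sp <- spec
      sp$validation$B <- grid$B[g]
      sp$imputation$M <- as.integer(grid$M[g])
      sp$seed <- NULL
      ests <- vapply(seq_len(n_runs), function(r)
        run_strategy(dat, sp)$estimates$e0632plus, numeric(1))
      stats::sd(ests)
    }, numeric(1))
    grid$sd[g] <- mean(sds)
  }
  grid
}

#' Performance on incomplete future patient data
#'
#' Fits the logistic model once on a complete data set of size `config$n`,
#' then evaluates it on large independent test sets carrying increasing
#' MCAR missingness, imputed (without the outcome, as at application stage)
#' using the test set alone as the imputation basis; the measure is
#' averaged over the `M` imputations.
#'
#' @param config a [sim_config()] (its `miss`/`mechanism` are ignored for
#'   the training data, which is complete).
#' @param miss_grid missingness proportions imposed on the test data.
#' @param n_test test-set size.
#' @param M imputations per test set.
#' @param measure measure label.
#' @param seed RNG seed.
#' @return A data frame with columns `miss` and `performance`.
#' @export
future_missingness_experiment <- function(config, miss_grid = c(0, 0.25, 0.5),
                                          n_test = 10000, M = 5,
                                          measure = "auc", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train <- generate_complete(config)
  ext <- fit_logistic(train$X, train$y)
  cfg_test <- config
  cfg_test$n <- as.integer(n_test)
  rows <- lapply(miss_grid, function(ms) {
    test <- generate_complete(cfg_test)
    if (ms > 0) {
      cfg_m <- cfg_test
      cfg_m$miss <- ms
      cfg_m$mechanism <- "MCAR"
      if (cfg_m$p0 > 0) cfg_m$miss0 <- ms
      test <- impose_missingness(test, cfg_m)
      imp <- run_mice(test, imputation_spec(M = M, include_outcome = FALSE))
      perf <- mean(vapply(imp$copies, function(Xc)
        compute_measure(measure, test$y, predict(ext, Xc), NULL,
                        config$frac), numeric(1)))
    } else {
      perf <- compute_measure(measure, test$y, predict(ext, test$X), NULL,
                              config$frac)
    }
    data.frame(miss = ms, performance = perf)
  })
  do.call(rbind, rows)
}
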