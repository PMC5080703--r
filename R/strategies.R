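#' Fit a maximum-likelihood logistic prediction model
#'
#' Thin wrapper around [stats::glm.fit()] returning a small model object.
#' A single-class training outcome is a degenerate split: `NULL` is
#' returned so callers can skip and count the split. Non-convergence
#' (e.g. complete separation) is flagged on the object; predictions are
#' clipped away from 0/1.
#'
#' @param X complete covariate matrix.
#' @param y binary outcome vector.
#' @return A `logistic_model` object, or `NULL` for a single-class outcome.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) return(NULL)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(coefficients = unname(fit$coefficients),
                 converged = fit$converged, separation = warned),
            class = "logistic_model")
}

#' Predict outcome probabilities from a fitted logistic model
#'
#' @param object a `logistic_model` from [fit_logistic()].
#' @param X covariate matrix with the same columns as used for fitting.
#' @param ... unused.
#' @return Predicted probabilities, clipped to `[1e-10, 1 - 1e-10]`.
#' @export
predict.logistic_model <- function(object, X, ...) {
  p <- stats::plogis(drop(cbind(1, as.matrix(X)) %*% object$coefficients))
  pmin(pmax(p, 1e-10), 1 - 1e-10)
}

#' Specification of a validation x imputation strategy
#'
#' Strategy names: `"val"` internal validation on complete data; `"val-mi"`
#' validation splits first, then multiple imputation of training and test
#' parts separately (outcome included, each part self-contained);
#' `"mi-val"` / `"mi-noy-val"` multiple imputation of the full data (with /
#' without the outcome) followed by validation on each imputed copy;
#' `"mi"` / `"mi-noy"` multiple imputation with Rubin-pooled apparent
#' performance only (no validation).
#'
#' @param name strategy name.
#' @param measure performance measure label (see [compute_measure()]).
#' @param validation list with `strategy` (`"BS"`, `"SS"`, `"CV"`,
#'   `"CVrep"`), `B` and `K`, passed to [draw_resamples()].
#' @param imputation an [imputation_spec()]; `include_outcome` is forced to
#'   match the strategy name.
#' @param baseline integer indices of the baseline covariate columns
#'   (required for added-performance measures).
#' @param frac outcome case frequency for NRI risk categories; defaults to
#'   the observed case fraction.
#' @param ci confidence-interval method: `"none"`, `"jiang"` (modified
#'   resampling percentile interval centred at the 0.632+ estimate) or
#'   `"delong"` (apparent-only strategies, AUC and change in AUC).
#' @param alpha CI level complement.
#' @param n_perm_noinfo permutations for the no-information performance of
#'   measures without a known null value (Brier, calibration).
#' @param seed optional RNG seed consumed at the start of [run_strategy()].
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name = c("val", "val-mi", "mi-val", "mi-noy-val",
                                   "mi", "mi-noy"),
                          measure = "auc",
                          validation = list(strategy = "BS", B = 10, K = 3),
                          imputation = imputation_spec(),
                          baseline = NULL, frac = NULL,
                          ci = c("none", "jiang", "delong"),
                          alpha = 0.05, n_perm_noinfo = 1000, seed = NULL) {
  name <- match.arg(name)
  ci <- match.arg(ci)
  measure <- match.arg(measure, measure_labels)
  validation <- utils::modifyList(list(strategy = "BS", B = 10, K = 3),
                                  validation)
  if (name %in% c("mi-noy-val", "mi-noy")) imputation$include_outcome <- FALSE
  if (name %in% c("val-mi", "mi-val", "mi")) imputation$include_outcome <- TRUE
  if (measure %in% added_measures && is.null(baseline))
    stop("added-performance measures require baseline covariate indices")
  if (ci == "jiang" &&
      (name %in% c("mi", "mi-noy") ||
       !(validation$strategy %in% c("BS", "SS"))))
    stop("the resampling percentile interval requires a BS or SS plan")
  if (ci == "delong" && !(name %in% c("mi", "mi-noy", "val")))
    stop("the DeLong interval applies to apparent-only strategies")
  structure(list(name = name, measure = measure, validation = validation,
                 imputation = imputation, baseline = baseline, frac = frac,
                 ci = ci, alpha = alpha, n_perm_noinfo = n_perm_noinfo,
                 seed = seed),
            class = "strategy_spec")
}

# subset an incomplete data set by row indices (duplicates allowed)
subset_incomplete <- function(data, idx) {
  structure(list(y = data$y[idx], X = data$X[idx, , drop = FALSE],
                 mask = data$mask[idx, , drop = FALSE],
                 X_complete = if (!is.null(data$X_complete))
                   data$X_complete[idx, , drop = FALSE] else NULL,
                 config = data$config, effect = data$effect),
            class = "incomplete_data")
}

#' Run a validation x imputation strategy on one data set
#'
#' Computes the apparent, out-of-bag, optimism-corrected, 0.632 and 0.632+
#' estimates of the chosen performance measure (for bootstrap/subsampling
#' plans; cross-validation plans report the plain CV estimate), combining
#' resampling and multiple imputation in the order prescribed by the
#' strategy name; see [strategy_spec()]. Averages are taken across the
#' B x M (resample, imputation) pairs before the estimators are applied.
#' Degenerate splits (single-class training outcome or non-evaluable test
#' measure) are skipped and counted; more than 20% skipped is an error.
#'
#' @param data an `incomplete_data` object (complete for `"val"`).
#' @param spec a [strategy_spec()].
#' @return An object of class `performance_report`: estimates, per-pair raw
#'   values, no-information performance, skipped-split count, optional
#'   confidence interval, diagnostics `R` and `w`, and the spec echo.
#' @export
run_strategy <- function(data, spec) {
  stopifnot(inherits(spec, "strategy_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ispec <- spec$imputation
  ispec$seed <- NULL                          # one seed at the top only
  y <- data$y
  X <- data$X
  n <- length(y)
  measure <- spec$measure
  frac <- if (is.null(spec$frac)) mean(y) else spec$frac
  base_cols <- spec$baseline
  need_base <- measure %in% added_measures
  vstrat <- spec$validation$strategy
  is_cv <- vstrat %in% c("CV", "CVrep")

  fit_models <- function(Xf, yf) {
    ext <- fit_logistic(Xf, yf)
    if (is.null(ext)) return(NULL)
    out <- list(ext = ext, base = NULL)
    if (need_base) {
      out$base <- fit_logistic(Xf[, base_cols, drop = FALSE], yf)
      if (is.null(out$base)) return(NULL)
    }
    out
  }
  eval_models <- function(models, Xe, ye) {
    p <- predict(models$ext, Xe)
    pb <- if (need_base)
      predict(models$base, Xe[, base_cols, drop = FALSE]) else NULL
    compute_measure(measure, ye, p, pb, frac)
  }
  apparent_preds <- list()                    # for permutation noinfo
  apparent_on <- function(Xc) {
    m <- fit_models(Xc, y)
    if (is.null(m)) stop("single-class outcome in the full data")
    apparent_preds[[length(apparent_preds) + 1L]] <<- predict(m$ext, Xc)
    eval_models(m, Xc, y)
  }

  if (spec$name == "val" && anyNA(X))
    stop("strategy 'val' requires complete data")
  if (spec$name %in% c("mi", "mi-noy")) {
    if (spec$ci == "delong")
      return(pooled_delong_ci(data, spec))
    imp <- run_mice(data, ispec)
    apparent <- mean(vapply(imp$copies, apparent_on, numeric(1)))
    return(structure(list(strategy = spec$name, measure = measure,
                          estimates = list(apparent = apparent),
                          raw = NULL, skipped = 0L, ci = NULL, spec = spec),
                     class = "performance_report"))
  }

  plan <- NULL
  raw <- list()
  skipped <- 0L
  total <- 0L
  record <- function(b, m, bsbs, bsorig, oob, rep) {
    total <<- total + 1L
    if (anyNA(c(bsbs, oob)) || (!is_cv && is.na(bsorig))) {
      skipped <<- skipped + 1L
      return(invisible())
    }
    raw[[length(raw) + 1L]] <<- c(b = b, m = m, rep = rep, bsbs = bsbs,
                                  bsorig = bsorig, oob = oob)
  }
  run_splits <- function(splits, Xc, Xorig, m_id) {
    for (s in seq_along(splits)) {
      sp <- splits[[s]]
      mods <- fit_models(Xc[sp$train, , drop = FALSE], y[sp$train])
      if (is.null(mods)) {
        total <<- total + 1L
        skipped <<- skipped + 1L
        next
      }
      bsbs <- eval_models(mods, Xc[sp$train, , drop = FALSE], y[sp$train])
      bsorig <- if (is_cv) NA_real_ else eval_models(mods, Xorig, y)
      oob <- eval_models(mods, Xc[sp$test, , drop = FALSE], y[sp$test])
      record(s, m_id, bsbs, bsorig, oob, sp$rep)
    }
  }

  if (spec$name == "val") {
    plan <- draw_resamples(n, vstrat, spec$validation$B, spec$validation$K)
    apparent <- apparent_on(X)
    run_splits(plan$splits, X, X, 1L)
  } else if (spec$name %in% c("mi-val", "mi-noy-val")) {
    imp <- run_mice(data, ispec)
    apparent <- mean(vapply(imp$copies, apparent_on, numeric(1)))
    for (m in seq_len(ispec$M)) {
      plan_m <- draw_resamples(n, vstrat, spec$validation$B,
                               spec$validation$K)
      run_splits(plan_m$splits, imp$copies[[m]], imp$copies[[m]], m)
    }
  } else {                                    # val-mi
    plan <- draw_resamples(n, vstrat, spec$validation$B, spec$validation$K)
    full_imp <- run_mice(data, ispec_with(ispec, include_outcome = TRUE))
    apparent <- mean(vapply(full_imp$copies, apparent_on, numeric(1)))
    for (b in seq_along(plan$splits)) {
      sp <- plan$splits[[b]]
      train_imp <- run_mice(subset_incomplete(data, sp$train),
                            ispec_with(ispec, include_outcome = TRUE))
      test_imp <- run_mice(subset_incomplete(data, sp$test),
                           ispec_with(ispec, include_outcome = TRUE))
      for (m in seq_len(ispec$M)) {
        mods <- fit_models(train_imp$copies[[m]], y[sp$train])
        if (is.null(mods)) {
          total <- total + 1L
          skipped <- skipped + 1L
          next
        }
        bsbs <- eval_models(mods, train_imp$copies[[m]], y[sp$train])
        bsorig <- if (is_cv) NA_real_ else
          eval_models(mods, full_imp$copies[[m]], y)
        oob <- eval_models(mods, test_imp$copies[[m]], y[sp$test])
        record(b, m, bsbs, bsorig, oob, sp$rep)
      }
    }
  }

  if (total > 0 && skipped / total > 0.2)
    stop(sprintf("%d of %d splits degenerate (> 20%%)", skipped, total))
  raw <- as.data.frame(do.call(rbind, raw))

  estimates <- list(apparent = apparent)
  diagnostics <- NULL
  noinfo <- NULL
  ci <- NULL
  if (is_cv) {
    per_rep <- tapply(raw$oob, raw[c("rep", "m")], mean)
    estimates$cv <- mean(per_rep, na.rm = TRUE)
  } else {
    noinfo <- if (measure == "auc") 0.5
      else if (measure %in% added_measures) 0
      else mean(vapply(apparent_preds, function(p)
        noinfo_performance(measure, y, p, spec$n_perm_noinfo), numeric(1)))
    estimates$oob <- mean(raw$oob)
    estimates$opt_corr <- optimism_corrected(apparent, mean(raw$bsbs),
                                             mean(raw$bsorig))
    estimates$e0632 <- estimate_0632(apparent, estimates$oob)
    plus <- estimate_0632plus(apparent, estimates$oob, noinfo)
    estimates$e0632plus <- as.numeric(plus)
    diagnostics <- list(R = attr(plus, "R"), w = attr(plus, "w"))
    if (spec$ci == "jiang")
      ci <- jiang_percentile_ci(raw$bsbs, apparent, estimates$e0632plus,
                                spec$alpha)
  }
  structure(list(strategy = spec$name, measure = measure,
                 estimates = estimates, raw = raw, noinfo = noinfo,
                 skipped = skipped, n_pairs = total, ci = ci,
                 diagnostics = diagnostics, spec = spec),
            class = "performance_report")
}

ispec_with <- function(ispec, include_outcome) {
  ispec$include_outcome <- include_outcome
  ispec
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance report: strategy %s, measure %s\n", x$strategy,
              x$measure))
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s %.4f\n", nm, x$estimates[[nm]]))
  if (!is.null(x$ci))
    cat(sprintf("  %d%% CI     [%.4f, %.4f]\n",
                round(100 * (1 - x$spec$alpha)), x$ci[1], x$ci[2]))
  if (!is.null(x$skipped) && x$skipped > 0)
    cat(sprintf("  (%d degenerate split(s) skipped)\n", x$skipped))
  invisible(x)
}

#' Modified resampling percentile confidence interval
#'
#' Percentile interval for a performance estimate: the deviations
#' `w_{b,m} = theta^{BS(b,m),BS(b,m)} - theta^{Orig,Orig}` of the resample
#' apparent values from the full-data apparent value are collected, their
#' `alpha/2` and `1 - alpha/2` percentiles `xi` taken, and the interval
#' `[point - xi_hi, point - xi_lo]` centred at the (0.632+) point estimate.
#'
#' @param resample_apparent per-(b,m) fit-and-evaluate-on-resample values.
#' @param apparent full-data apparent performance.
#' @param point the point estimate to centre the interval at.
#' @param alpha level complement (default 0.05).
#' @return `c(lower, upper)`.
#' @export
jiang_percentile_ci <- function(resample_apparent, apparent, point,
                                alpha = 0.05) {
  if (length(resample_apparent) < 2)
    stop("at least 2 resample apparent values are required")
  if (length(resample_apparent) < 40)
    warning("fewer than 40 resample values; percentile interval unstable")
  w <- resample_apparent - apparent
  xi <- stats::quantile(w, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(point - xi[2], point - xi[1])
}

# DeLong placement values for one score vector: V10 (cases), V01 (controls)
delong_components <- function(y, p) {
  case <- p[y == 1]
  ctrl <- p[y == 0]
  n1 <- length(case)
  n0 <- length(ctrl)
  if (n1 < 2 || n0 < 2) stop("DeLong variance needs >= 2 cases and controls")
  r_all <- rank(c(case, ctrl))
  V10 <- (r_all[seq_len(n1)] - rank(case)) / n0
  V01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(ctrl)) / n1
  list(auc = mean(V10), V10 = V10, V01 = V01, n1 = n1, n0 = n0)
}

# DeLong variance of the AUC (or of delta AUC when p_base given)
delong_variance <- function(y, p, p_base = NULL) {
  a <- delong_components(y, p)
  if (is.null(p_base))
    return(stats::var(a$V10) / a$n1 + stats::var(a$V01) / a$n0)
  b <- delong_components(y, p_base)
  stats::var(a$V10 - b$V10) / a$n1 + stats::var(a$V01 - b$V01) / a$n0
}

#' Apparent-performance confidence interval from DeLong's variance, pooled
#' across imputations by Rubin's rules
#'
#' For the apparent-only strategies: each imputed copy yields an AUC (or
#' change in AUC) and its DeLong variance; Rubin's rules give the pooled
#' estimate and total variance, and a normal-approximation interval.
#' On complete data the result is the plain DeLong interval.
#'
#' @param data an `incomplete_data` object.
#' @param spec a [strategy_spec()] with name `"mi"`, `"mi-noy"` or `"val"`
#'   and measure `"auc"` or `"dauc"`.
#' @return A `performance_report` whose `ci` is the pooled interval.
#' @export
pooled_delong_ci <- function(data, spec) {
  if (!spec$measure %in% c("auc", "dauc"))
    stop("DeLong intervals are available for AUC and change in AUC")
  y <- data$y
  base_cols <- spec$baseline
  copies <- if (anyNA(data$X)) {
    ispec <- spec$imputation
    run_mice(data, ispec)$copies
  } else rep(list(data$X), 1L)
  ests <- vars <- numeric(length(copies))
  for (m in seq_along(copies)) {
    Xc <- copies[[m]]
    ext <- fit_logistic(Xc, y)
    if (is.null(ext)) stop("single-class outcome")
    p <- predict(ext, Xc)
    if (spec$measure == "auc") {
      ests[m] <- auc(y, p)
      vars[m] <- delong_variance(y, p)
    } else {
      base <- fit_logistic(Xc[, base_cols, drop = FALSE], y)
      pb <- predict(base, Xc[, base_cols, drop = FALSE])
      ests[m] <- delta_auc(y, p, pb)
      vars[m] <- delong_variance(y, p, pb)
    }
  }
  pooled <- pool_rubin(ests, vars)
  z <- stats::qnorm(1 - spec$alpha / 2)
  ci <- c(pooled$estimate - z * sqrt(pooled$variance),
          pooled$estimate + z * sqrt(pooled$variance))
  structure(list(strategy = spec$name, measure = spec$measure,
                 estimates = list(apparent = pooled$estimate,
                                  variance = pooled$variance),
                 raw = data.frame(m = seq_along(copies), estimate = ests,
                                  variance = vars),
                 skipped = 0L, ci = ci, spec = spec),
            class = "performance_report")
}
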