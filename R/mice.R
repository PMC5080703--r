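#' Imputation settings
#'
#' @param M number of imputations.
#' @param include_outcome include the outcome in the imputation models
#'   (strategy MI) or not (strategy MI(-y)).
#' @param n_donors donor-pool size for predictive mean matching.
#' @param n_iterations chained-equation sweeps over the incomplete variables.
#' @param seed optional RNG seed used by [run_mice()].
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(M = 5, include_outcome = TRUE, n_donors = 5,
                            n_iterations = 5, seed = NULL) {
  stopifnot(M >= 1, n_donors >= 1, n_iterations >= 1)
  structure(list(M = as.integer(M), include_outcome = include_outcome,
                 n_donors = as.integer(n_donors),
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "imputation_spec")
}

# transformation menu; each entry is forward / inverse pair
transform_menu <- list(
  raw  = list(f = identity, inv = identity),
  log  = list(f = log, inv = exp),
  cbrt = list(f = function(x) sign(x) * abs(x)^(1 / 3),
              inv = function(x) x^3),
  sqrt = list(f = sqrt, inv = function(x) x^2)
)

# Shapiro-Wilk W; stats::shapiro.test is limited to 5000 values, so larger
# vectors are reduced to 5000 evenly spaced order statistics (deterministic).
shapiro_w <- function(x) {
  if (length(x) > 5000)
    x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  stats::shapiro.test(x)$statistic
}

#' Choose the normality-improving transformation for one variable
#'
#' Compares the observed values raw and under natural log, cubic root and
#' square root transformations by their Shapiro-Wilk W statistic and returns
#' the transformation with maximal W. Log is eligible only for strictly
#' positive and square root only for non-negative observed values.
#'
#' @param x numeric vector, possibly with missing entries; at least 3
#'   distinct observed values are required.
#' @return A list with `name`, the forward (`f`) and inverse (`inv`)
#'   transformation, and the named vector `W` of candidate statistics.
#' @export
choose_transformation <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3) stop("fewer than 3 observed values")
  if (diff(range(obs)) == 0) stop("constant variable; no transformation defined")
  cand <- c("raw", "cbrt")
  if (all(obs > 0)) cand <- c(cand, "log")
  if (all(obs >= 0)) cand <- c(cand, "sqrt")
  W <- vapply(cand, function(nm) {
    tx <- transform_menu[[nm]]$f(obs)
    if (diff(range(tx)) == 0) return(-Inf)
    unname(shapiro_w(tx))
  }, numeric(1))
  best <- cand[which.max(W)]
  c(transform_menu[[best]], list(name = best, W = W))
}

#' Predictive-mean-matching imputation of one variable
#'
#' Fits a Bayesian linear regression of the observed target values on the
#' predictors, draws the residual variance from a scaled inverse chi-squared
#' distribution and the coefficients from their normal posterior, and
#' computes predictions for observed rows with the least-squares coefficients
#' and for missing rows with the drawn coefficients (type-1 matching). Each
#' missing entry is then replaced by the observed value of one donor drawn
#' uniformly from the `n_donors` observed rows with closest predictions.
#'
#' @param x numeric target vector with `NA`s for missing entries.
#' @param predictors numeric matrix of fully observed predictors (an
#'   intercept is added internally).
#' @param n_donors donor-pool size.
#' @param posterior_draw draw coefficients/variance from the posterior
#'   (`TRUE`, the imputation default) or use the least-squares point estimate
#'   for the missing-row predictions too (`FALSE`; deterministic matching).
#' @param ridge relative ridge added to the cross-product matrix when it is
#'   numerically singular.
#' @return `x` with missing entries filled by observed donor values.
#' @export
draw_pmm_imputation <- function(x, predictors, n_donors = 5,
                                posterior_draw = TRUE, ridge = 1e-5) {
  mis <- which(is.na(x))
  if (length(mis) == 0) return(x)
  obs <- which(!is.na(x))
  if (length(obs) == 0) stop("empty donor pool: no observed values")
  Xd <- cbind(1, as.matrix(predictors))
  Xo <- Xd[obs, , drop = FALSE]
  yo <- x[obs]
  S <- crossprod(Xo)
  Sty <- crossprod(Xo, yo)
  beta_hat <- tryCatch(solve(S, Sty), error = function(e) {
    warning("collinear predictors; ridge-stabilized imputation model")
    solve(S + diag(ridge * mean(diag(S)), ncol(S)), Sty)
  })
  res <- yo - drop(Xo %*% beta_hat)
  df <- max(length(obs) - ncol(Xo), 1)
  if (posterior_draw) {
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    Sinv <- tryCatch(solve(S), error = function(e)
      solve(S + diag(ridge * mean(diag(S)), ncol(S))))
    Rch <- chol(Sinv + diag(1e-12, ncol(Sinv)))
    beta_draw <- drop(beta_hat + sqrt(sigma2) * crossprod(Rch, stats::rnorm(ncol(Xo))))
  } else {
    beta_draw <- drop(beta_hat)
  }
  pred_obs <- drop(Xo %*% beta_hat)
  pred_mis <- drop(Xd[mis, , drop = FALSE] %*% beta_draw)
  k <- min(n_donors, length(obs))
  # donor pool: the k observed rows with closest predictions, found by a
  # two-pointer scan over the sorted predictions (order() is stable, so
  # exact prediction ties fall back to row order)
  o <- order(pred_obs)
  po <- pred_obs[o]
  yo_sorted <- yo[o]
  pos <- findInterval(pred_mis, po)
  n_po <- length(po)
  picks <- integer(k)
  chosen <- sample.int(k, length(mis), replace = TRUE)
  for (i in seq_along(mis)) {
    lo <- pos[i]
    hi <- pos[i] + 1L
    for (t in seq_len(k)) {
      dlo <- if (lo >= 1L) pred_mis[i] - po[lo] else Inf
      dhi <- if (hi <= n_po) po[hi] - pred_mis[i] else Inf
      if (dlo <= dhi) {
        picks[t] <- lo
        lo <- lo - 1L
      } else {
        picks[t] <- hi
        hi <- hi + 1L
      }
    }
    x[mis[i]] <- yo_sorted[picks[chosen[i]]]
  }
  x
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Each incomplete covariate is first assigned the normality-improving
#' transformation chosen by [choose_transformation()] on its observed values.
#' Working values are kept on the transformed scale, initialised by random
#' draws from the observed values, and updated over `n_iterations` sweeps in
#' which every incomplete covariate is imputed by [draw_pmm_imputation()]
#' given all other covariates (plus the outcome when
#' `spec$include_outcome`). The inverse transformation is applied once on
#' output; because donors are observed values this is lossless.
#'
#' @param data an `incomplete_data` object (or list with `y`, `X`, `mask`).
#' @param spec an [imputation_spec()].
#' @return An object of class `completed_datasets`: list with `copies` (list
#'   of `M` complete covariate matrices), `y`, and `transform_log`.
#' @export
run_mice <- function(data, spec = imputation_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  X <- data$X
  y <- data$y
  n <- nrow(X)
  incomplete <- which(colSums(is.na(X)) > 0)
  if (length(incomplete) == 0) {
    copies <- rep(list(X), spec$M)
    return(structure(list(copies = copies, y = y, transform_log = list()),
                     class = "completed_datasets"))
  }
  n_obs <- colSums(!is.na(X))
  short <- incomplete[n_obs[incomplete] < 3]
  if (length(short))
    stop("variable(s) with fewer than 3 observed values: ",
         paste(colnames(X)[short], collapse = ", "))
  # per-variable transformation, chosen once on the observed values
  tlog <- list()
  W <- X
  for (j in incomplete) {
    tr <- choose_transformation(X[, j])
    tlog[[colnames(X)[j]]] <- list(name = tr$name, W = tr$W)
    W[, j] <- tr$f(X[, j])
    tlog[[colnames(X)[j]]]$inv <- tr$inv
  }
  # visit order: increasing missingness count, ties by column index
  visit <- incomplete[order(n_obs[incomplete], decreasing = TRUE)]
  copies <- vector("list", spec$M)
  for (m in seq_len(spec$M)) {
    work <- W
    for (j in visit) {                        # initial fill from observed
      mis <- is.na(work[, j])
      obs_vals <- work[!mis, j]
      work[mis, j] <- obs_vals[sample.int(length(obs_vals), sum(mis),
                                          replace = TRUE)]
    }
    for (it in seq_len(spec$n_iterations)) {
      for (j in visit) {
        target <- W[, j]                      # NAs restored each sweep
        preds <- work[, -j, drop = FALSE]
        if (spec$include_outcome) preds <- cbind(preds, y)
        work[, j] <- draw_pmm_imputation(target, preds,
                                         n_donors = spec$n_donors)
      }
    }
    out <- work
    for (j in incomplete) {
      nm <- colnames(X)[j]
      out[, j] <- tlog[[nm]]$inv(out[, j])
      out[!is.na(X[, j]), j] <- X[!is.na(X[, j]), j]  # exact observed values
    }
    copies[[m]] <- out
  }
  structure(list(copies = copies, y = y,
                 transform_log = lapply(tlog, function(t) t[c("name", "W")])),
            class = "completed_datasets")
}

#' Pool estimates (and variances) across imputations by Rubin's rules
#'
#' @param estimates numeric vector of the M per-imputation point estimates.
#' @param variances optional vector of the M per-imputation variances.
#' @return If `variances` is `NULL`, the pooled point estimate (mean).
#'   Otherwise a list with `estimate` and `variance`, the total variance
#'   being the mean within-imputation variance plus `(1 + 1/M)` times the
#'   between-imputation variance.
#' @export
pool_rubin <- function(estimates, variances = NULL) {
  if (length(estimates) == 0) stop("no estimates to pool")
  est <- mean(estimates)
  if (is.null(variances)) return(est)
  stopifnot(length(variances) == length(estimates), all(variances >= 0))
  M <- length(estimates)
  between <- if (M > 1) stats::var(estimates) else 0
  list(estimate = est, variance = mean(variances) + (1 + 1 / M) * between)
}
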