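#' Simulation configuration
#'
#' Describes one simulation setting: sample size, covariate structure,
#' outcome case frequency, theoretical AUC of the covariate set, and the
#' missingness mechanism and degree. Two situations are supported. In
#' situation 1 a single set of `p` covariates carries the whole effect and
#' `auc` is its theoretical AUC. In situation 2 (`p0 > 0`) a baseline set of
#' `p0` covariates attains theoretical AUC `auc0` on its own and the
#' additional set of `p` covariates raises the theoretical AUC of the joint
#' model to `auc0 + dauc`.
#'
#' @param n sample size.
#' @param p number of (additional, in situation 2) covariates.
#' @param auc theoretical AUC of the covariate set (situation 1). Ignored
#'   when `p0 > 0`; use `auc0` and `dauc` instead.
#' @param frac outcome case probability, in (0, 0.5].
#' @param rho pairwise correlation within the (additional) covariate set.
#' @param miss proportion of missing values imposed on the (additional)
#'   covariate set, in \[0, 1).
#' @param mechanism missingness mechanism: `"MCAR"`, `"MAR"` or `"MARblock"`.
#' @param p0 number of baseline covariates (0 switches situation 2 off).
#' @param auc0 theoretical AUC of the baseline set alone (situation 2).
#' @param rho0 pairwise correlation within the baseline set.
#' @param miss0 proportion of missing values in the baseline set.
#' @param dauc theoretical added AUC of the additional set (situation 2).
#' @param seed optional RNG seed stored with the configuration and used by
#'   [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, p, auc = 0.5, frac = 0.5, rho = 0, miss = 0,
                       mechanism = c("MCAR", "MAR", "MARblock"),
                       p0 = 0, auc0 = NULL, rho0 = 0, miss0 = 0,
                       dauc = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(n >= 2, p >= 1, p0 >= 0)
  if (frac <= 0 || frac > 0.5)
    stop("frac must lie in (0, 0.5]")
  if (rho < 0 || rho >= 1 || rho0 < 0 || rho0 >= 1)
    stop("correlations must lie in [0, 1)")
  if (miss < 0 || miss >= 1 || miss0 < 0 || miss0 >= 1)
    stop("missingness proportions must lie in [0, 1)")
  if (p0 > 0) {
    if (is.null(auc0) || is.null(dauc))
      stop("situation 2 (p0 > 0) requires auc0 and dauc")
    check_auc_domain(auc0)
    check_auc_domain(auc0 + dauc)
    if (dauc < 0) stop("dauc must be non-negative")
  } else {
    check_auc_domain(auc)
  }
  structure(list(n = as.integer(n), p = as.integer(p), auc = auc,
                 frac = frac, rho = rho, miss = miss, mechanism = mechanism,
                 p0 = as.integer(p0), auc0 = auc0, rho0 = rho0,
                 miss0 = miss0, dauc = dauc, seed = seed),
            class = "sim_config")
}

check_auc_domain <- function(a) {
  if (a < 0.5 || a >= 1) stop("theoretical AUC must lie in [0.5, 1)")
  invisible(a)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  n = %d, frac = %g, mechanism = %s\n", x$n, x$frac,
              x$mechanism))
  if (x$p0 > 0)
    cat(sprintf("  baseline: p0 = %d (rho0 = %g, auc0 = %g, miss0 = %g)\n",
                x$p0, x$rho0, x$auc0, x$miss0),
        sprintf("  additional: p = %d (rho = %g, dauc = %g, miss = %g)\n",
                x$p, x$rho, x$dauc, x$miss))
  else
    cat(sprintf("  p = %d, rho = %g, auc = %g, miss = %g\n", x$p, x$rho,
                x$auc, x$miss))
  invisible(x)
}

# Exchangeable-correlation covariance with unit variances.
exch_sigma <- function(p, rho) {
  s <- matrix(rho, p, p)
  diag(s) <- 1
  s
}

# Covariance of the full covariate vector: block diagonal over the baseline
# and additional sets (sets are mutually uncorrelated).
config_sigma <- function(config) {
  s1 <- exch_sigma(config$p, config$rho)
  if (config$p0 == 0) return(s1)
  s <- matrix(0, config$p0 + config$p, config$p0 + config$p)
  s[seq_len(config$p0), seq_len(config$p0)] <- exch_sigma(config$p0,
                                                          config$rho0)
  s[config$p0 + seq_len(config$p), config$p0 + seq_len(config$p)] <- s1
  s
}

# Theoretical AUC of a mean-difference vector dmu under covariance sigma:
# Phi(0.5 * sqrt(dmu' Sigma^-1 dmu)).
theoretical_auc <- function(dmu, sigma) {
  q <- drop(crossprod(dmu, solve(sigma, dmu)))
  stats::pnorm(0.5 * sqrt(q))
}

#' Solve the common per-covariate effect size for a target theoretical AUC
#'
#' With a common class-mean difference applied to every covariate, the
#' theoretical AUC of the covariate set is
#' \deqn{AUC = \Phi(\tfrac12 \sqrt{\Delta\mu^T \Sigma^{-1} \Delta\mu}),}
#' where \eqn{\Delta\mu} is the vector of class-mean differences and
#' \eqn{\Sigma} the covariate covariance. This function finds the scalar
#' \eqn{\Delta\mu \ge 0} such that the target AUC is attained, by a
#' numerical root search ([stats::uniroot()]).
#'
#' @param auc_target theoretical AUC in \[0.5, 1).
#' @param sigma covariance matrix (unit variances expected).
#' @param p number of covariates; defaults to `nrow(sigma)` and must match.
#' @param tol solver tolerance on the root.
#' @return The scalar common mean difference.
#' @export
solve_effect_size <- function(auc_target, sigma, p = nrow(sigma),
                              tol = 1e-10) {
  check_auc_domain(auc_target)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != p || ncol(sigma) != p)
    stop("sigma must be a p x p matrix")
  if (auc_target == 0.5) return(0)
  s <- sum(solve(sigma))       # 1' Sigma^-1 1; errors on singular sigma
  if (s <= 0) stop("sigma is not positive definite on the common direction")
  f <- function(d) stats::pnorm(0.5 * d * sqrt(s)) - auc_target
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

# Effect specification for a configuration: the (stacked) mean-difference
# vector, the implied logistic coefficients gamma = Sigma^-1 dmu, and the
# per-set scalar effects.
effect_spec <- function(config) {
  sigma <- config_sigma(config)
  if (config$p0 == 0) {
    dmu_scalar <- solve_effect_size(config$auc, sigma)
    dmu <- rep(dmu_scalar, config$p)
    out <- list(dmu = dmu, dmu1 = dmu_scalar, dmu0 = NULL)
  } else {
    sigma0 <- exch_sigma(config$p0, config$rho0)
    dmu0 <- solve_effect_size(config$auc0, sigma0)
    target <- config$auc0 + config$dauc
    sigma1 <- exch_sigma(config$p, config$rho)
    q0 <- dmu0^2 * sum(solve(sigma0))
    s1 <- sum(solve(sigma1))
    # blocks are independent, so the quadratic form is additive
    f <- function(d1) stats::pnorm(0.5 * sqrt(q0 + d1^2 * s1)) - target
    if (f(0) >= 0) {
      d1 <- 0
    } else {
      upper <- 1
      while (f(upper) < 0) upper <- upper * 2
      d1 <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
    }
    dmu <- c(rep(dmu0, config$p0), rep(d1, config$p))
    out <- list(dmu = dmu, dmu1 = d1, dmu0 = dmu0)
  }
  out$sigma <- sigma
  out$gamma <- drop(solve(sigma, out$dmu))
  out
}

#' Generate a complete data set with a prescribed theoretical AUC
#'
#' Outcomes are i.i.d. Bernoulli(`frac`). Covariates are multivariate normal
#' with unit variances and exchangeable within-set correlation; half the
#' class-mean difference solved by [solve_effect_size()] is added to cases'
#' covariate values and subtracted from controls'.
#'
#' @param config a [sim_config()].
#' @return An `incomplete_data` object whose mask is all-zero: a list with
#'   elements `y`, `X`, `mask`, `X_complete`, `config` and `effect`.
#' @export
generate_complete <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- effect_spec(config)
  n <- config$n
  ptot <- config$p0 + config$p
  y <- stats::rbinom(n, 1L, config$frac)
  X <- MASS::mvrnorm(n, mu = rep(0, ptot), Sigma = eff$sigma)
  X <- matrix(X, nrow = n)                     # guard n = 1 drop
  shift <- ifelse(y == 1, 0.5, -0.5)
  X <- X + outer(shift, eff$dmu)
  colnames(X) <- paste0("x", seq_len(ptot))
  structure(list(y = y, X = X, mask = matrix(0L, n, ptot,
                                             dimnames = list(NULL, colnames(X))),
                 X_complete = X, config = config, effect = eff),
            class = "incomplete_data")
}

#' Build an incomplete_data container from raw pieces
#'
#' @param y binary outcome vector (no missing values).
#' @param X covariate matrix, possibly containing `NA`s.
#' @param X_complete optional ground-truth complete matrix.
#' @param config optional [sim_config()] the data came from.
#' @return An `incomplete_data` object; the mask is derived from `is.na(X)`.
#' @export
incomplete_data <- function(y, X, X_complete = NULL, config = NULL) {
  X <- as.matrix(X)
  if (anyNA(y)) stop("the outcome must be fully observed")
  if (length(y) != nrow(X)) stop("y and X sizes differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mask <- matrix(as.integer(is.na(X)), nrow(X), ncol(X),
                 dimnames = dimnames(X))
  structure(list(y = as.integer(y), X = X, mask = mask,
                 X_complete = X_complete, config = config, effect = NULL),
            class = "incomplete_data")
}

#' @export
print.incomplete_data <- function(x, ...) {
  cat(sprintf("Incomplete data set: n = %d, p = %d, cases = %d, %d missing cells (%.1f%%)\n",
              nrow(x$X), ncol(x$X), sum(x$y), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Solve a missingness-model intercept for a target missingness proportion
#'
#' Finds the intercept \eqn{\beta_{0j}} such that the mean over observations
#' of \eqn{P(M_{ij}=1) = \mathrm{logistic}(\beta_{0j} + \eta_i)} equals
#' `miss`, where `eta` collects all non-intercept terms of the logistic
#' missingness model.
#'
#' @param eta numeric vector of per-observation linear predictors excluding
#'   the intercept.
#' @param miss target missingness proportion in (0, 1).
#' @param tol root tolerance.
#' @return The scalar intercept.
#' @export
solve_missingness_intercept <- function(eta, miss, tol = 1e-10) {
  if (miss <= 0 || miss >= 1) stop("miss must lie in (0, 1)")
  f <- function(b0) mean(stats::plogis(b0 + eta)) - miss
  lo <- -40; hi <- 40
  while (f(lo) > 0 && lo > -1e6) lo <- lo * 2
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0)
    stop("could not bracket the missingness intercept; eta range ",
         paste(signif(range(eta), 4), collapse = " to "))
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# Draw the structural (non-intercept) part of the MAR / MARblock missingness
# model for one covariate set occupying columns `cols` of the full matrix.
draw_missingness_model <- function(config, cols, p_total) {
  p_set <- length(cols)
  mech <- config$mechanism
  model <- list(mechanism = mech, cols = cols, outcome_coef = 2)
  if (mech == "MAR") {
    model$beta1 <- c(0, sample(c(-1, 1), p_set - 1, replace = TRUE))
    model$beta2 <- c(0, rep(2, p_set - 1))[seq_len(p_set)]
    if (p_total == 1) {
      model$beta2[] <- 0                      # no other covariate available
      model$partner <- NA_integer_
    } else {
      model$partner <- vapply(cols, function(j)
        resample(setdiff(seq_len(p_total), j), 1L), integer(1))
    }
  } else if (mech == "MARblock") {
    if (p_set < 2)
      stop("MARblock requires at least 2 covariates in the set")
    repeat {
      blocks <- sample.int(3L, p_set, replace = TRUE)
      ok <- all(vapply(unique(blocks), function(b)
        length(setdiff(cols, cols[blocks == b])) > 0, logical(1)))
      if (ok) break
    }
    model$blocks <- blocks
    model$block_partner <- vapply(sort(unique(blocks)), function(b)
      resample(setdiff(cols, cols[blocks == b]), 1L), integer(1))
    names(model$block_partner) <- sort(unique(blocks))
    model$block_partner_coef <- 10
  }
  model
}

# sample() misbehaves on length-1 x; classic guard
resample <- function(x, size) x[sample.int(length(x), size)]

#' Impose missingness on a complete data set
#'
#' Masks exactly `round(n * miss)` entries per covariate (per covariate set in
#' situation 2). For MCAR the masked cells are uniform draws; for MAR the
#' probability of missingness of covariate \eqn{j} follows
#' \eqn{\mathrm{logistic}(\beta_{0j} + \beta_{1j} M_{i,j-1} +
#' \beta_{2j} X_{i k_j} + 2 y_i)} with intercepts solved so the mean
#' probability equals `miss`; for MARblock covariates are randomly assigned
#' to three blocks and \eqn{\mathrm{logistic}(\beta_{0j} + 10 X_{i k_b} +
#' 2 y_i)} with a common partner covariate \eqn{k_b} outside each block.
#' Cells are masked by weighted sampling without replacement with
#' probabilities proportional to \eqn{P(M_{ij}=1)}, which guarantees the
#' exact missingness count. The outcome is never masked.
#'
#' @param data a complete `incomplete_data` object (all-zero mask).
#' @param config the [sim_config()]; defaults to `data$config`.
#' @return The data with `X` masked (`NA`s), the 0/1 `mask` filled in, and
#'   the fitted missingness model attached as `$miss_model`.
#' @export
impose_missingness <- function(data, config = data$config) {
  stopifnot(inherits(data, "incomplete_data"))
  if (any(data$mask != 0L)) stop("data must be complete (all-zero mask)")
  n <- length(data$y)
  ptot <- ncol(data$X)
  sets <- list()
  if (config$p0 > 0)
    sets <- c(sets, list(list(cols = seq_len(config$p0),
                              miss = config$miss0)))
  sets <- c(sets, list(list(cols = config$p0 + seq_len(config$p),
                            miss = config$miss)))
  models <- list()
  for (set in sets) {
    if (set$miss == 0) next
    k <- round(n * set$miss)
    if (k > n - 2)
      stop("miss = ", set$miss, " would leave fewer than 2 observed values")
    if (config$mechanism == "MCAR") {
      for (j in set$cols) {
        idx <- sample.int(n, k)
        data$mask[idx, j] <- 1L
      }
      models <- c(models, list(list(mechanism = "MCAR", cols = set$cols)))
    } else {
      model <- draw_missingness_model(config, set$cols, ptot)
      model$beta0 <- numeric(length(set$cols))
      prev_mask <- rep(0L, n)
      for (s in seq_along(set$cols)) {
        j <- set$cols[s]
        if (config$mechanism == "MAR") {
          eta <- model$beta1[s] * prev_mask + 2 * data$y
          if (model$beta2[s] != 0)
            eta <- eta + model$beta2[s] * data$X_complete[, model$partner[s]]
        } else {                              # MARblock
          b <- model$blocks[s]
          eta <- model$block_partner_coef *
            data$X_complete[, model$block_partner[[as.character(b)]]] +
            2 * data$y
        }
        b0 <- solve_missingness_intercept(eta, set$miss)
        model$beta0[s] <- b0
        prob <- stats::plogis(b0 + eta)
        idx <- sample.int(n, k, prob = prob)
        data$mask[idx, j] <- 1L
        prev_mask <- as.integer(seq_len(n) %in% idx)
      }
      models <- c(models, list(model))
    }
  }
  data$X[data$mask == 1L] <- NA_real_
  data$miss_model <- models
  data
}

#' Simulate one incomplete data set from a configuration
#'
#' Convenience wrapper: seeds the RNG (if `config$seed` or `seed` is given),
#' generates complete data and imposes missingness.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return An `incomplete_data` object.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  data <- generate_complete(config)
  if (config$miss > 0 || (config$p0 > 0 && config$miss0 > 0))
    data <- impose_missingness(data, config)
  data
}

#' Write a data set as CSV plus a JSON manifest
#'
#' The CSV has a header row, outcome column `y`, covariates `x1..xp`, and
#' missing entries as empty fields. The manifest records the configuration,
#' solved effect sizes, missingness-model coefficients and seed so the data
#' set can be regenerated.
#'
#' @param data an `incomplete_data` object.
#' @param path CSV output path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- data.frame(y = data$y, data$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  manifest <- list(config = unclass(data$config),
                   dmu = data$effect$dmu, gamma = data$effect$gamma,
                   miss_model = data$miss_model,
                   package_version = as.character(utils::packageVersion("valimpute")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a data set written by [write_dataset()]
#'
#' @param path CSV path (outcome column `y`, covariates in the remaining
#'   columns, empty fields as missing).
#' @return An `incomplete_data` object.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  if (!"y" %in% names(df)) stop("no outcome column 'y' in ", path)
  incomplete_data(df$y, as.matrix(df[setdiff(names(df), "y")]))
}
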