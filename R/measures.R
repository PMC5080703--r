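#' Area under the ROC curve (concordance)
#'
#' The probability that a randomly chosen case receives a higher predicted
#' probability than a randomly chosen control; ties count one half.
#' Computed from midranks (equivalent to exhaustive pair counting).
#'
#' @param y binary outcome vector (0/1).
#' @param p_hat predicted probabilities or scores.
#' @return AUC in \[0, 1\], or `NA_real_` when only one outcome class is
#'   present (degenerate-measure sentinel, never silently 0.5).
#' @export
auc <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("y and p_hat lengths differ")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between outcomes and predicted probabilities;
#' lower is better.
#'
#' @inheritParams auc
#' @return The Brier score.
#' @export
brier <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("y and p_hat lengths differ")
  mean((y - p_hat)^2)
}

#' Calibration intercept and slope
#'
#' Maximum-likelihood logistic regression of the observed outcomes on the
#' logit of the predicted probabilities. Perfectly calibrated predictions
#' give intercept 0 and slope 1. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before the logit.
#'
#' @inheritParams auc
#' @return Named vector `c(intercept, slope)` with attribute `converged`;
#'   non-convergence (e.g. perfect separation) is flagged, not hidden.
#'   `NA`s when only one outcome class is present.
#' @export
calibration_coefficients <- function(y, p_hat) {
  stopifnot(length(y) == length(p_hat))
  if (length(unique(y)) < 2)
    return(structure(c(intercept = NA_real_, slope = NA_real_),
                     converged = FALSE))
  lp <- stats::qlogis(pmin(pmax(p_hat, 1e-12), 1 - 1e-12))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, lp), y, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(c(intercept = fit$coefficients[1], slope = fit$coefficients[2]),
            names = c("intercept", "slope"),
            converged = fit$converged && !warned)
}

#' Risk categories from the outcome case frequency
#'
#' Three categories `[0, frac/2]`, `(frac/2, 3*frac/2]`, `(3*frac/2, 1]`
#' built around the case frequency, so that one cutoff lies below and one
#' above the disease risk.
#'
#' @param frac outcome case frequency, at most 0.5.
#' @return The two cutpoints `c(frac/2, 3*frac/2)`.
#' @export
risk_categories <- function(frac) {
  if (frac <= 0 || frac > 0.5) stop("frac must lie in (0, 0.5]")
  c(frac / 2, 3 * frac / 2)
}

#' Categorical net reclassification improvement
#'
#' Difference between the proportions of observations moving into a more
#' correct risk category (cases up, controls down) and a less correct one,
#' summed over the two classes (per-class proportions), with three
#' categories defined by [risk_categories()].
#'
#' @inheritParams auc
#' @param p_hat_base baseline-model predicted probabilities.
#' @param frac outcome case frequency defining the category cutpoints;
#'   defaults to the observed case fraction.
#' @return NRI in \[-2, 2\], or `NA_real_` if a class is absent.
#' @export
nri_categorical <- function(y, p_hat, p_hat_base, frac = mean(y)) {
  if (is.null(p_hat_base)) stop("baseline predictions are required")
  stopifnot(length(y) == length(p_hat), length(y) == length(p_hat_base))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
  cuts <- risk_categories(frac)
  cat_new <- findInterval(p_hat, cuts, left.open = TRUE)
  cat_old <- findInterval(p_hat_base, cuts, left.open = TRUE)
  up <- cat_new > cat_old
  down <- cat_new < cat_old
  (mean(up[y == 1]) - mean(down[y == 1])) +
    (mean(down[y == 0]) - mean(up[y == 0]))
}

#' Continuous (category-free) net reclassification improvement
#'
#' Same construction as [nri_categorical()], with "up"/"down" meaning any
#' increase/decrease of the predicted probability; ties contribute zero.
#'
#' @inheritParams nri_categorical
#' @return Continuous NRI in \[-2, 2\], or `NA_real_` if a class is absent.
#' @export
nri_continuous <- function(y, p_hat, p_hat_base) {
  if (is.null(p_hat_base)) stop("baseline predictions are required")
  stopifnot(length(y) == length(p_hat), length(y) == length(p_hat_base))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
  s <- sign(p_hat - p_hat_base)
  (mean(s[y == 1] > 0) - mean(s[y == 1] < 0)) +
    (mean(s[y == 0] < 0) - mean(s[y == 0] > 0))
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes: the rise in mean predicted
#' probability among cases minus the rise among controls, extended versus
#' baseline model. Equals the NRI integrated over all risk cutoffs.
#'
#' @inheritParams nri_categorical
#' @return IDI in \[-1, 1\], or `NA_real_` if a class is absent.
#' @export
idi <- function(y, p_hat, p_hat_base) {
  if (is.null(p_hat_base)) stop("baseline predictions are required")
  stopifnot(length(y) == length(p_hat), length(y) == length(p_hat_base))
  if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
  (mean(p_hat[y == 1]) - mean(p_hat_base[y == 1])) -
    (mean(p_hat[y == 0]) - mean(p_hat_base[y == 0]))
}

#' Change in AUC between extended and baseline model
#'
#' @inheritParams nri_categorical
#' @return `auc(y, p_hat) - auc(y, p_hat_base)`, `NA_real_` if degenerate.
#' @export
delta_auc <- function(y, p_hat, p_hat_base) {
  if (is.null(p_hat_base)) stop("baseline predictions are required")
  auc(y, p_hat) - auc(y, p_hat_base)
}

# measure registry ----------------------------------------------------------

measure_labels <- c("auc", "brier", "calib_intercept", "calib_slope",
                    "dauc", "nri", "nricont", "idi")

# measures comparing an extended against a baseline model
added_measures <- c("dauc", "nri", "nricont", "idi")

# is a larger value better for this measure?
measure_direction <- function(measure) {
  switch(measure,
         brier = FALSE,
         calib_intercept = NA, calib_slope = NA,   # target values 0 / 1
         TRUE)
}

#' Compute a named performance measure
#'
#' Dispatcher over the implemented (added) performance measures. Degenerate
#' inputs (single outcome class for discrimination/reclassification
#' measures) yield `NA_real_`, which downstream averaging layers skip and
#' count.
#'
#' @param measure one of `"auc"`, `"brier"`, `"calib_intercept"`,
#'   `"calib_slope"`, `"dauc"`, `"nri"`, `"nricont"`, `"idi"`.
#' @inheritParams nri_categorical
#' @return The scalar measure value.
#' @export
compute_measure <- function(measure, y, p_hat, p_hat_base = NULL,
                            frac = NULL) {
  measure <- match.arg(measure, measure_labels)
  if (measure %in% added_measures && is.null(p_hat_base))
    stop("measure '", measure, "' requires baseline predictions")
  switch(measure,
         auc = auc(y, p_hat),
         brier = brier(y, p_hat),
         calib_intercept = unname(calibration_coefficients(y, p_hat)[1]),
         calib_slope = unname(calibration_coefficients(y, p_hat)[2]),
         dauc = delta_auc(y, p_hat, p_hat_base),
         nri = nri_categorical(y, p_hat, p_hat_base,
                               frac = if (is.null(frac)) mean(y) else frac),
         nricont = nri_continuous(y, p_hat, p_hat_base),
         idi = idi(y, p_hat, p_hat_base))
}
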