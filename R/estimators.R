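#' No-information performance of a measure
#'
#' Expected performance when predictions are unrelated to the outcomes:
#' 0.5 for AUC, 0 for the added measures (change in AUC, NRI, continuous
#' NRI, IDI), and for the remaining measures (Brier score, calibration
#' coefficients) the average measure over random permutations of the
#' predictions (1000 permutations by default).
#'
#' @param measure measure label (see [compute_measure()]).
#' @param y outcomes (permutation mode).
#' @param p_hat predictions (permutation mode).
#' @param n_perm number of random permutations.
#' @return The no-information value of the measure.
#' @export
noinfo_performance <- function(measure, y = NULL, p_hat = NULL,
                               n_perm = 1000) {
  measure <- match.arg(measure, measure_labels)
  if (measure == "auc") return(0.5)
  if (measure %in% added_measures) return(0)
  if (is.null(y) || is.null(p_hat))
    stop("permutation-based no-information value requires y and p_hat")
  vals <- vapply(seq_len(n_perm), function(i)
    compute_measure(measure, y, p_hat[sample.int(length(p_hat))]),
    numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Ordinary optimism-corrected performance estimate
#'
#' The optimism is the average apparent performance in the resamples minus
#' the average performance of resample-fitted models on the original data;
#' it is subtracted from the apparent performance of the full-data model.
#'
#' @param apparent full-data apparent performance.
#' @param train_train average fit-and-evaluate performance on the resamples.
#' @param train_orig average performance of resample-fitted models evaluated
#'   on the original data.
#' @return `apparent - (train_train - train_orig)`.
#' @export
optimism_corrected <- function(apparent, train_train, train_orig) {
  apparent - (train_train - train_orig)
}

#' Bootstrap 0.632 performance estimate
#'
#' @param apparent full-data apparent performance.
#' @param oob average out-of-bag performance.
#' @return `0.368 * apparent + 0.632 * oob`.
#' @export
estimate_0632 <- function(apparent, oob) {
  0.368 * apparent + 0.632 * oob
}

#' Bootstrap 0.632+ performance estimate
#'
#' Weighted combination `(1 - w) * apparent + w * oob` with
#' `w = 0.632 / (1 - 0.368 * R)` and relative overfitting rate
#' `R = (oob - apparent) / (noinfo - apparent)`. `R` is clipped to
#' \[0, 1\] (so `w` stays in \[0.632, 1\]); when `noinfo == apparent` no
#' overfitting is estimable and `R` is set to 0, reproducing the plain
#' 0.632 estimate.
#'
#' @inheritParams estimate_0632
#' @param noinfo no-information performance (see [noinfo_performance()]).
#' @return The 0.632+ estimate, with diagnostics `R` and `w` attached as
#'   attributes.
#' @export
estimate_0632plus <- function(apparent, oob, noinfo) {
  den <- noinfo - apparent
  R <- if (!is.finite(den) || den == 0) 0 else (oob - apparent) / den
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  structure((1 - w) * apparent + w * oob, R = R, w = w)
}
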