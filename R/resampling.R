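#' Draw train/test index splits for internal validation
#'
#' Supported strategies: `"BS"` bootstrap (train drawn with replacement,
#' size `n`; test = out-of-bag complement of the distinct train indices),
#' `"SS"` subsampling (train = `round(0.632 * n)` distinct indices, test =
#' complement), `"CV"` simple K-fold cross-validation (`B` forced to 1) and
#' `"CVrep"` repeated K-fold cross-validation (`B` repetitions). Folds
#' partition the observations with sizes differing by at most one
#' (remainders go to the first folds of a random permutation). Bootstrap
#' draws whose out-of-bag set would be empty are redrawn.
#'
#' @param n number of observations.
#' @param strategy one of `"BS"`, `"SS"`, `"CV"`, `"CVrep"`.
#' @param B number of resamples (BS/SS) or repetitions (CVrep).
#' @param K number of folds (CV strategies).
#' @param seed optional RNG seed.
#' @return An object of class `resampling_plan`: list with `strategy`, `n`,
#'   `B`, `K` and `splits`, each split a list with 1-based `train`, `test`
#'   and repetition id `rep`.
#' @export
draw_resamples <- function(n, strategy = c("BS", "SS", "CV", "CVrep"),
                           B = 1, K = 3, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  if (B < 1) stop("B must be at least 1")
  splits <- list()
  if (strategy %in% c("CV", "CVrep")) {
    if (K < 2 || K > n) stop("K must satisfy 2 <= K <= n")
    reps <- if (strategy == "CV") 1L else as.integer(B)
    for (r in seq_len(reps)) {
      perm <- sample.int(n)
      sizes <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
      stops <- cumsum(sizes)
      starts <- c(1, stops[-K] + 1)
      for (k in seq_len(K)) {
        test <- sort(perm[starts[k]:stops[k]])
        splits[[length(splits) + 1L]] <-
          list(train = sort(setdiff(seq_len(n), test)), test = test, rep = r)
      }
    }
    B <- reps
  } else {
    for (b in seq_len(B)) {
      if (strategy == "BS") {
        repeat {
          train <- sample.int(n, n, replace = TRUE)
          test <- setdiff(seq_len(n), unique(train))
          if (length(test) > 0) break
          message("redrawing bootstrap sample with empty out-of-bag set")
        }
      } else {                                # SS
        train <- sort(sample.int(n, round(0.632 * n)))
        test <- setdiff(seq_len(n), train)
      }
      splits[[b]] <- list(train = train, test = sort(test), rep = b)
    }
  }
  structure(list(strategy = strategy, n = as.integer(n), B = as.integer(B),
                 K = if (strategy %in% c("CV", "CVrep")) as.integer(K) else NA_integer_,
                 seed = seed, splits = splits),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("Resampling plan: %s, n = %d, %d splits\n", x$strategy, x$n,
              length(x$splits)))
  invisible(x)
}

#' Serialize a resampling plan to JSON (1-based indices)
#'
#' @param plan a `resampling_plan`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
plan_to_json <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
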