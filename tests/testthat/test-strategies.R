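test_that("logistic fitting recovers the generating coefficients", {
  cfg <- sim_config(n = 20000, p = 3, auc = 0.74, frac = 0.5, seed = 14)
  d <- simulate_dataset(cfg)
  fit <- fit_logistic(d$X, d$y)
  expect_equal(unname(fit$coefficients[-1]), d$effect$gamma, tolerance = 0.1)
  # null effect: coefficients near zero, predictions near the case fraction
  cfg0 <- sim_config(n = 20000, p = 2, auc = 0.5, frac = 0.25, seed = 15)
  d0 <- simulate_dataset(cfg0)
  fit0 <- fit_logistic(d0$X, d0$y)
  expect_equal(unname(fit0$coefficients[-1]), c(0, 0), tolerance = 0.07)
  expect_equal(mean(predict(fit0, d0$X)), 0.25, tolerance = 0.02)
  # degenerate and separable inputs
  expect_null(fit_logistic(cbind(1:4), rep(1, 4)))
  sep <- fit_logistic(cbind(c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_true(sep$separation)
})

test_that("all strategies reduce to complete-data validation on complete data", {
  cfg <- sim_config(n = 150, p = 4, auc = 0.66, frac = 0.5, miss = 0, seed = 16)
  d <- simulate_dataset(cfg)
  mk <- function(name, M) strategy_spec(name, measure = "auc",
                                        validation = list(strategy = "BS", B = 8),
                                        imputation = imputation_spec(M = M),
                                        seed = 99)
  ref <- run_strategy(d, mk("val", 1))
  for (args in list(list("val-mi", 3), list("mi-val", 1),
                    list("mi-noy-val", 1))) {
    got <- run_strategy(d, mk(args[[1]], args[[2]]))
    expect_identical(got$estimates, ref$estimates, info = args[[1]])
  }
  # and with an added-performance measure
  mk2 <- function(name) strategy_spec(name, measure = "dauc",
                                      validation = list(strategy = "SS", B = 8),
                                      imputation = imputation_spec(M = 1),
                                      baseline = 1:2, seed = 100)
  expect_identical(run_strategy(d, mk2("val-mi"))$estimates,
                   run_strategy(d, mk2("val"))$estimates)
})

test_that("reported averages pool the per-(b,m) raw values", {
  d <- make_small_mar_data()
  sp <- strategy_spec("mi-val", validation = list(strategy = "BS", B = 4),
                      imputation = imputation_spec(M = 3), seed = 31)
  r <- run_strategy(d, sp)
  expect_equal(nrow(r$raw), 12)
  expect_equal(r$estimates$oob, mean(r$raw$oob))
  expect_equal(r$estimates$opt_corr,
               r$estimates$apparent - (mean(r$raw$bsbs) - mean(r$raw$bsorig)))
  expect_equal(r$estimates$e0632,
               0.368 * r$estimates$apparent + 0.632 * r$estimates$oob)
  expect_gte(r$diagnostics$w, 0.632)
  # determinism: same data, spec and seed give the same report
  expect_equal(run_strategy(d, sp)$estimates, r$estimates)
})

test_that("cross-validation strategies report the plain CV estimate", {
  d <- make_small_mar_data()
  sp <- strategy_spec("mi-val", validation = list(strategy = "CVrep",
                                                  B = 2, K = 3),
                      imputation = imputation_spec(M = 2), seed = 41)
  r <- run_strategy(d, sp)
  expect_named(r$estimates, c("apparent", "cv"))
  expect_equal(nrow(r$raw), 2 * 3 * 2)
  expect_equal(r$estimates$cv, mean(tapply(r$raw$oob,
                                           r$raw[c("rep", "m")], mean)))
})

test_that("the percentile interval is centred at the point estimate", {
  # all resample apparents equal the full apparent: degenerate interval
  expect_equal(suppressWarnings(jiang_percentile_ci(rep(0.7, 10), 0.7, 0.65)),
               c(0.65, 0.65))
  # symmetric deviations: point +/- d
  w <- 0.7 + c(-0.1, -0.05, 0, 0.05, 0.1)
  ci <- suppressWarnings(jiang_percentile_ci(w, 0.7, 0.6, alpha = 0.5))
  expect_equal(mean(ci), 0.6)
  expect_equal(ci[2] - ci[1], 2 * unname(quantile(w - 0.7, 0.75)))
  expect_error(jiang_percentile_ci(0.7, 0.7, 0.7), "at least 2")
  # within a report: lower <= point <= upper
  d <- make_small_mar_data()
  sp <- strategy_spec("val-mi", validation = list(strategy = "BS", B = 40),
                      imputation = imputation_spec(M = 1), ci = "jiang",
                      seed = 51)
  r <- run_strategy(d, sp)
  expect_lte(r$ci[1], r$estimates$e0632plus)
  expect_gte(r$ci[2], r$estimates$e0632plus)
})

test_that("DeLong variance matches the brute-force placement oracle and pROC", {
  y <- c(0, 0, 1, 1)
  p <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(valimpute:::delong_variance(y, p), delong_oracle(y, p))
  set.seed(61)
  y2 <- rbinom(60, 1, 0.4)
  p2 <- runif(60)
  expect_equal(valimpute:::delong_variance(y2, p2), delong_oracle(y2, p2))
  roc <- pROC::roc(y2, p2, quiet = TRUE, direction = "<")
  expect_equal(valimpute:::delong_variance(y2, p2), pROC::var(roc))
})

test_that("pooled DeLong interval reduces to the plain interval on complete data", {
  cfg <- sim_config(n = 150, p = 2, auc = 0.74, frac = 0.5, seed = 71)
  d <- simulate_dataset(cfg)
  sp <- strategy_spec("val", ci = "delong")
  r <- pooled_delong_ci(d, sp)
  fit <- fit_logistic(d$X, d$y)
  p <- predict(fit, d$X)
  expect_equal(r$estimates$apparent, auc(d$y, p))
  expect_equal(r$estimates$variance, valimpute:::delong_variance(d$y, p))
  z <- qnorm(0.975)
  expect_equal(r$ci, r$estimates$apparent +
                 c(-z, z) * sqrt(r$estimates$variance))
  # incomplete data: interval pools M per-imputation estimates
  d2 <- make_small_mar_data()
  sp2 <- strategy_spec("mi", imputation = imputation_spec(M = 3),
                       ci = "delong", seed = 72)
  r2 <- run_strategy(d2, sp2)
  expect_equal(nrow(r2$raw), 3)
  expect_equal(r2$estimates$apparent, mean(r2$raw$estimate))
  expect_gt(r2$estimates$variance, mean(r2$raw$variance)) # between-imp term
})

test_that("invalid strategy configurations are rejected", {
  expect_error(strategy_spec("val-mi", measure = "dauc"), "baseline")
  expect_error(strategy_spec("mi", ci = "jiang"), "BS or SS")
  expect_error(strategy_spec("val-mi", ci = "delong"), "apparent-only")
  cfg <- sim_config(n = 60, p = 2, auc = 0.6, miss = 0.25,
                    mechanism = "MCAR", seed = 81)
  d <- simulate_dataset(cfg)
  expect_error(run_strategy(d, strategy_spec("val")), "complete")
})
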