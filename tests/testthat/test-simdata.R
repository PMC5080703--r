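test_that("effect-size solver matches closed forms and round-trips", {
  # p = 1: AUC = Phi(dmu / 2), so dmu = 2 * qnorm(auc)
  expect_equal(solve_effect_size(0.66, diag(1)), 2 * qnorm(0.66),
               tolerance = 1e-8)
  # independent covariates: dmu' Sigma^-1 dmu = p * dmu^2
  expect_equal(solve_effect_size(0.82, diag(5)), 2 * qnorm(0.82) / sqrt(5),
               tolerance = 1e-8)
  expect_identical(solve_effect_size(0.5, diag(3)), 0)
  # round-trip over the simulation grid, independent and correlated
  for (target in c(0.5, 0.58, 0.66, 0.74, 0.82)) {
    for (rho in c(0, 0.25)) {
      sigma <- matrix(rho, 10, 10); diag(sigma) <- 1
      d <- solve_effect_size(target, sigma)
      expect_equal(pnorm(0.5 * sqrt(d^2 * sum(solve(sigma)))), target,
                   tolerance = 1e-6)
    }
  }
  expect_error(solve_effect_size(0.4, diag(2)), "AUC")
  expect_error(solve_effect_size(1, diag(2)), "AUC")
})

test_that("situation 2 solves baseline and added effects jointly", {
  cfg <- sim_config(n = 100, p = 5, frac = 0.5, p0 = 2, auc0 = 0.6,
                    dauc = 0.08, rho0 = 0, rho = 0.25)
  eff <- valimpute:::effect_spec(cfg)
  sigma0 <- diag(2)
  expect_equal(pnorm(0.5 * sqrt(sum((eff$dmu0 * solve(sigma0, rep(1, 2))) *
                                      eff$dmu0))), 0.6, tolerance = 1e-6)
  # full vector attains auc0 + dauc
  expect_equal(valimpute:::theoretical_auc(eff$dmu, eff$sigma), 0.68,
               tolerance = 1e-6)
  # baseline block keeps its own effect size
  expect_equal(eff$dmu[1:2], rep(eff$dmu0, 2))
})

test_that("generated complete data attain the implied AUC and case fraction", {
  cfg <- sim_config(n = 10000, p = 1, auc = 0.74, frac = 0.25, seed = 11)
  d <- simulate_dataset(cfg)
  expect_equal(mean(d$y), 0.25, tolerance = 0.015)
  # the solved shift dmu = 2 qnorm(auc) makes the single covariate's
  # population AUC equal the binormal value Phi(dmu / sqrt(2))
  expect_equal(auc(d$y, d$X[, 1]), pnorm(sqrt(2) * qnorm(0.74)),
               tolerance = 0.01)
  # null effect: class means coincide
  cfg0 <- sim_config(n = 10000, p = 2, auc = 0.5, frac = 0.5, seed = 12)
  d0 <- simulate_dataset(cfg0)
  expect_lt(abs(mean(d0$X[d0$y == 1, 1]) - mean(d0$X[d0$y == 0, 1])), 0.06)
})

test_that("missingness intercept solver hits the target mean probability", {
  expect_equal(solve_missingness_intercept(rep(0, 50), 0.5), 0,
               tolerance = 1e-8)
  expect_equal(solve_missingness_intercept(rep(0, 50), 0.25), qlogis(0.25),
               tolerance = 1e-8)
  set.seed(4)
  eta <- rnorm(300, sd = 2)
  b0 <- solve_missingness_intercept(eta, 0.375)
  expect_equal(mean(plogis(b0 + eta)), 0.375, tolerance = 1e-8)
})

test_that("masking is exact per covariate for every mechanism", {
  for (mech in c("MCAR", "MAR", "MARblock")) {
    cfg <- sim_config(n = 200, p = 10, auc = 0.66, frac = 0.5, miss = 0.25,
                      mechanism = mech, seed = 21)
    d <- simulate_dataset(cfg)
    expect_equal(unname(colSums(d$mask)), rep(50, 10), info = mech)
    expect_true(all(is.na(d$X[d$mask == 1])))
    expect_true(all(!is.na(d$X[d$mask == 0])))
    expect_equal(d$X[d$mask == 0], d$X_complete[d$mask == 0])
  }
  # miss = 0 leaves the mask untouched
  cfg0 <- sim_config(n = 50, p = 2, auc = 0.6, miss = 0, seed = 2)
  expect_equal(sum(simulate_dataset(cfg0)$mask), 0)
})

test_that("MCAR masking is independent of outcome and values", {
  cfg <- sim_config(n = 5000, p = 2, auc = 0.74, frac = 0.5, miss = 0.375,
                    mechanism = "MCAR", seed = 31)
  d <- simulate_dataset(cfg)
  m <- d$mask[, 1]
  expect_lt(abs(cor(m, d$y, method = "kendall")), 0.05)
  expect_lt(abs(cor(m, d$X_complete[, 1], method = "kendall")), 0.05)
})

test_that("MAR masking is enriched in cases through the outcome term", {
  cfg <- sim_config(n = 10000, p = 3, auc = 0.5, frac = 0.5, miss = 0.375,
                    mechanism = "MAR", seed = 41)
  d <- simulate_dataset(cfg)
  masked <- d$mask == 1
  y_mat <- matrix(d$y, nrow(d$mask), ncol(d$mask))
  expect_gt(mean(y_mat[masked]), mean(y_mat[!masked]))
})

test_that("MARblock co-missingness exceeds MCAR at equal miss", {
  overlap <- function(mask) {
    # mean pairwise Jaccard overlap of per-covariate masked sets
    p <- ncol(mask)
    vals <- c()
    for (j in seq_len(p - 1)) for (k in (j + 1):p) {
      a <- which(mask[, j] == 1); b <- which(mask[, k] == 1)
      vals <- c(vals, length(intersect(a, b)) / length(union(a, b)))
    }
    mean(vals)
  }
  cfgB <- sim_config(n = 500, p = 6, auc = 0.66, miss = 0.25,
                     mechanism = "MARblock", seed = 51)
  cfgM <- sim_config(n = 500, p = 6, auc = 0.66, miss = 0.25,
                     mechanism = "MCAR", seed = 51)
  ovB <- mean(replicate(10, overlap(simulate_dataset(cfgB, seed = NULL)$mask)))
  ovM <- mean(replicate(10, overlap(simulate_dataset(cfgM, seed = NULL)$mask)))
  expect_gt(ovB, ovM)
})

test_that("simulation is reproducible from the seed and round-trips CSV", {
  cfg <- sim_config(n = 60, p = 4, auc = 0.66, miss = 0.25,
                    mechanism = "MAR", seed = 61)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$mask, d2$mask)
  path <- tempfile(fileext = ".csv")
  write_dataset(d1, path)
  d3 <- read_dataset(path)
  expect_equal(d3$y, d1$y)
  expect_equal(unname(d3$mask), unname(d1$mask))
  expect_equal(d3$X, d1$X, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".manifest.json")))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n = 100, p = 1, auc = 0.45), "AUC")
  expect_error(sim_config(n = 100, p = 1, auc = 0.6, frac = 0.7), "frac")
  expect_error(sim_config(n = 100, p = 1, auc = 0.6, miss = 1), "missingness")
  cfg <- sim_config(n = 10, p = 1, auc = 0.6, miss = 0.9, mechanism = "MCAR")
  expect_error(simulate_dataset(cfg), "fewer than 2 observed")
  cfg1 <- sim_config(n = 100, p = 1, auc = 0.6, miss = 0.25,
                     mechanism = "MARblock")
  expect_error(simulate_dataset(cfg1), "MARblock")
})
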