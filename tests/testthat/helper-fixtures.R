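# shared fixtures and independent oracles

# exhaustive pair-counting AUC (ties count one half); O(n^2) reference
auc_pair_oracle <- function(y, p) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  if (length(cases) == 0 || length(ctrls) == 0) return(NA_real_)
  conc <- 0
  for (a in cases) for (b in ctrls)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(cases) * length(ctrls))
}

# brute-force DeLong placement values (loops, no ranks)
delong_oracle <- function(y, p) {
  cases <- p[y == 1]
  ctrls <- p[y == 0]
  V10 <- vapply(cases, function(a)
    mean((a > ctrls) + 0.5 * (a == ctrls)), numeric(1))
  V01 <- vapply(ctrls, function(b)
    mean((cases > b) + 0.5 * (cases == b)), numeric(1))
  var(V10) / length(cases) + var(V01) / length(ctrls)
}

# all permutations of seq_len(n) (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(sub, n, after = k - 1)
  }
  out
}

# small incomplete data set used by several tests
make_small_mar_data <- function(seed = 42, n = 120, p = 3, auc = 0.66,
                                miss = 0.25) {
  cfg <- sim_config(n = n, p = p, auc = auc, frac = 0.5, miss = miss,
                    mechanism = "MAR", seed = seed)
  simulate_dataset(cfg)
}
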