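# Independent brute-force oracles and small scenario builders shared by the
# test suite.  Oracles are deliberately naive (explicit loops over the
# definitions) and share no code with the implementation paths they check.

# Day-by-day accumulation oracles -------------------------------------------

oracle_dhw <- function(hs, threshold) {
  w <- hs[(length(hs) - 83):length(hs)]
  s <- 0
  for (v in w) if (is.finite(v) && v >= threshold) s <- s + v
  s / 7
}

oracle_dhm <- function(hs_monthly, threshold) {
  w <- hs_monthly[(length(hs_monthly) - 11):length(hs_monthly)]
  s <- 0
  for (v in w) if (is.finite(v) && v >= threshold) s <- s + v
  s
}

oracle_dcw <- function(sst, mmm) {
  w <- sst[(length(sst) - 83):length(sst)]
  s <- 0
  for (v in w) {
    cs <- mmm - v
    if (is.finite(cs) && cs >= 0) s <- s + cs
  }
  s / 7
}

# Exhaustive evaluation-threshold search ------------------------------------

oracle_best_threshold <- function(probs, labels) {
  cand <- sort(unique(probs))
  best_t <- NA_real_; best_sum <- -Inf
  for (t in cand) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
    tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
    s <- tp / (tp + fn) + tn / (tn + fp)
    if (s > best_sum + 1e-12) { best_sum <- s; best_t <- t }
  }
  list(threshold = best_t, tss = best_sum - 1)
}

oracle_confusion <- function(probs, labels, t) {
  pred <- probs >= t
  c(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

# Small scenario builders ----------------------------------------------------

tiny_scenario <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(4, 4), years = c(2000, 2005),
                   n_observations = 200, noise_sd = 0.2,
                   interannual_sd = 0.3, seed = 42)
  do.call(synthetic_scenario, utils::modifyList(defaults, args))
}

# Deterministic cube with no stochastic components at all (caller
# overrides take precedence).
flat_scenario <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, interannual_sd = 0, trend = 0,
                                 lat_gradient = 0), list(...))
  do.call(tiny_scenario, args)
}

# Covariate draw with its own seed, kept outside the generator substreams.
with_seed_df <- function(seed, n = 2000) {
  set.seed(seed)
  data.frame(dhw = runif(n, 0, 5), u = runif(n, 0, 1))
}

# Pair of columns with an exact prescribed sample correlation, built by
# Gram-Schmidt on realized draws.
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  z <- z - mean(z)
  z <- z - sum(z * x) / sum(x * x) * x   # orthogonal to x
  z <- z / sd(z)
  y <- r * x + sqrt(1 - r^2) * z
  data.frame(x = x, y = y)
}
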