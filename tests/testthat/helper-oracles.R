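# Independent oracles and fixture builders used across the suite.

# Random binary series over K unnamed categories.
rand_series <- function(T, K = 2, p = 0.5, id = "r") {
  m <- matrix(rbinom(T * K, 1, p), nrow = T,
              dimnames = list(NULL, paste0("k", seq_len(K))))
  behavior_series(id, m)
}

# Brute-force lag-1 contingency: explicit interval-by-interval loop.
oracle_lag_counts <- function(a, b) {
  n11 <- n10 <- n01 <- n00 <- 0
  for (t in seq_len(length(a) - 1)) {
    x <- a[t]; y <- b[t + 1]
    if (x == 1 && y == 1) n11 <- n11 + 1
    else if (x == 1 && y == 0) n10 <- n10 + 1
    else if (x == 0 && y == 1) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

# Partial correlation oracle on ranks via residualization: Pearson
# correlation of the residuals of rank(x) ~ rank(z) and rank(y) ~ rank(z).
oracle_partial_resid <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  cor(resid(lm(rx ~ rz)), resid(lm(ry ~ rz)))
}

# Two-column series from explicit first/second streams.
two_stream <- function(a, b, id = "d") {
  behavior_series(id, cbind(first = a, second = b))
}

# A tiny all-zero-free MCAM-like sample for pipeline tests.
small_sample <- function(n = 6, T = 30, seed = 11) {
  generate_sample(generator_config(n_dyads = n, T = T, seed = seed))
}
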