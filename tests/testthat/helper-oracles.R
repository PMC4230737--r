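# Independent brute-force oracles used to validate the statistical paths.

# Two-sided rank-sum p-value by exhaustive enumeration of all
# choose(m+n, m) group-label assignments. Valid for tie-free data.
perm_ranksum_oracle <- function(x, y) {
  pool <- c(x, y)
  r <- rank(pool)
  m <- length(x)
  n_tot <- length(pool)
  mu <- m * (n_tot + 1) / 2
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n_tot, m)
  w_null <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Textbook Pearson correlation.
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}
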