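# independent statistical oracles shared by the unit and acceptance tests

# two-sided Mann-Whitney p by direct enumeration over value assignments,
# with U computed from pairwise comparisons (not ranks)
mw_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(vals), n1)
  devs <- apply(combos, 2L, function(i) abs(u_of(vals[i], vals[-i]) - mu))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

# standardized tie-corrected rank-sum statistic of one group pair,
# on the sqrt(2)-scaled studentized-range scale
sd_pair_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V > 0) sqrt(2) * abs(W - E) / sqrt(V) else 0
}
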