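# Independent oracles, written before the implementations they check and
# kept free of the package's code paths.

# Exhaustive hypergeometric enumeration for the two-sided Fisher p of one
# 2x2 table: probabilities of every table sharing the observed margins are
# computed directly from binomial coefficients; the two-sided p sums those
# not exceeding the observed table's probability (1 + 1e-7 relative guard).
fisher_oracle <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  r2 <- n21 + n22
  c1 <- n11 + n21
  n <- r1 + r2
  if (r1 == 0 || c1 == 0 || c1 == n || r1 == n) {
    return(1)
  }
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  pobs <- pr[n11 - x[1] + 1]
  # clamp like the implementation: extreme tables underflow the density
  min(max(sum(pr[pr <= pobs * (1 + 1e-7)]), .Machine$double.xmin), 1)
}

# Vectorized enumeration oracle: two-sided p for EVERY table with fixed
# margins (r1, r2, c1), indexed by the support of n11. Used for the
# complete sweep, where computing the whole support at once is exact and
# cheap (sorted cumulative sums).
fisher_oracle_margins <- function(r1, r2, c1) {
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  ord <- order(pr)
  cum <- cumsum(pr[ord])
  idx <- findInterval(pr * (1 + 1e-7), pr[ord])
  pmin(cum[idx], 1)
}

# Exact two-sided binomial test by direct summation of binomial pmf terms
# computed from binomial coefficients (probability-mass convention).
binom_oracle <- function(x1, n, prob) {
  k <- 0:n
  pr <- exp(lchoose(n, k) + k * log(prob) + (n - k) * log1p(-prob))
  min(max(sum(pr[pr <= pr[x1 + 1] * (1 + 1e-7)]), .Machine$double.xmin), 1)
}

# Benjamini-Hochberg step-up written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[ord] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
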