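# Independent oracles used to validate the statistical operations.

# Benjamini-Hochberg step-up, written directly from the closed form
# q_i = min_{j >= rank(i)} p_(j) * m / j, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# upper-tail hypergeometric probability by combinatorial enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# running-sum enrichment score computed the slow, literal way: walk the whole
# list position by position
es_walk_oracle <- function(scores, hit_pos, weight = 1) {
  N <- length(scores)
  hit <- seq_len(N) %in% hit_pos
  w <- abs(scores)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (N - sum(hit)))
  if (sum(w[hit]) == 0) inc[hit] <- 1 / sum(hit)
  walk <- cumsum(inc)
  hi <- max(walk)
  lo <- min(walk)
  # same positive-preference tie rule as the implementation
  if (hi >= -lo - 1e-9) hi else lo
}
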