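# Independent brute-force oracles, deliberately written in different terms
# than the package implementations.

# Mann-Whitney: U counted directly as #{(i,j): x_i > y_j} (+1/2 per tie);
# exact two-sided p by enumerating every assignment of the pooled values to
# the two groups and doubling the smaller tail.
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_mw_u(x, y)
  sets <- combn(length(pooled), n1)
  us <- apply(sets, 2, function(ix) oracle_mw_u(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Wilcoxon signed-rank: enumerate every sign pattern via bit expansion.
oracle_wsr_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(b) {
    bits <- as.integer(intToBits(b))[seq_len(n)]
    sum(r[bits == 1L])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# random small logical masks for polygonization properties
random_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# a small, quick field configuration used across tests
small_config <- function(...) {
  simulation_config(field_width_px = 420, field_height_px = 420, ...)
}

MIDPOINT_THRESHOLDS <- c(DAPI = 2100, CD3 = 2100, B220 = 2100)
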