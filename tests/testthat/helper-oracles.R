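# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Naive double-loop evaluation of the per-filament spatial autocorrelation.
naive_autocorrelation <- function(values, n_max) {
  L <- length(values)
  mu <- sum(values) / L
  s2 <- sum((values - mu)^2) / L
  g <- numeric(n_max + 1)
  for (n in 0:n_max) {
    acc <- 0
    for (m in seq_len(L - n)) acc <- acc + (values[m + n] - mu) * (values[m] - mu)
    g[n + 1] <- acc / (L - n) / s2
  }
  g
}

# 1D optimal-transport cost with unit distance between adjacent bins, via
# sorted unit-mass matching: each count histogram is expanded to n_b * n_a
# unit masses at its bin positions (cross-multiplying totals handles unequal
# totals exactly), sorted, and matched rank by rank.
transport_emd <- function(counts_a, counts_b) {
  pos_a <- rep(seq_along(counts_a), counts_a)
  pos_b <- rep(seq_along(counts_b), counts_b)
  ua <- rep(pos_a, each = length(pos_b))   # N*M unit masses each
  ub <- rep(pos_b, each = length(pos_a))
  sum(abs(sort(ua) - sort(ub))) / (length(pos_a) * length(pos_b))
}

# Random count histogram on `b` bins with the given total.
random_counts <- function(b, total) {
  as.vector(stats::rmultinom(1, total, stats::runif(b, 0.05, 1)))
}

counts_as_histogram <- function(counts) {
  build_histogram(rep(seq_along(counts), counts),
                  edges = seq(0.5, length(counts) + 0.5))
}

# Expected per-string run-length counts of Bernoulli(p) strings of length L,
# by exhaustive enumeration of all 2^L outcomes (feasible for small L).
enumerate_run_lengths <- function(L, p) {
  v <- 0:(2^L - 1)
  bits <- matrix(as.integer(intToBits(v)), nrow = 32)[seq_len(L), , drop = FALSE]
  out <- numeric(L)
  for (i in seq_along(v)) {
    b <- bits[, i]
    pr <- prod(ifelse(b == 1, p, 1 - p))
    r <- rle(b)
    for (k in r$lengths[r$values == 1]) out[k] <- out[k] + pr
  }
  out
}

# Small deterministic filament set used by several tests.
toy_set <- function() {
  filament_set(data.frame(
    run_id = "r1",
    filament_id = rep(1:2, c(4, 5)),
    cell_index = c(0:3, 0:4),
    fluorescence = c(1, 2, 1, 2, 5, 6, 7, 6, 5)))
}
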