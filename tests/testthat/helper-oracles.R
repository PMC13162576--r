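# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately re-derive each quantity from its definition and share no
# code with the implementation.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, mapped to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(m * p[ord][js] / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Topological overlap by the O(n^3) triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    denom <- min(k[i], k[j]) + 1 - a[i, j]
    w[i, j] <- if (denom <= 0) 0 else (l + a[i, j]) / denom
  }
  w
}

# One-sided (greater) Fisher/hypergeometric tail by exhaustive enumeration of
# overlap counts, using only choose().
fisher_tail_oracle <- function(k, K, n, N) {
  kk <- max(k, 0):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# PERMANOVA pseudo-F from pairwise squared Euclidean distances, re-derived.
pseudo_F_oracle <- function(x, g) {
  # x: samples in columns; g: factor
  d2 <- as.matrix(dist(t(x)))^2
  N <- length(g)
  sst <- sum(d2[upper.tri(d2)]) / N
  ssw <- 0
  for (lev in levels(g)) {
    i <- which(g == lev)
    ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i, drop = FALSE])]) / length(i)
  }
  ((sst - ssw) / (nlevels(g) - 1)) / (ssw / (N - nlevels(g)))
}

# small labelled random log2 matrix
random_log2_matrix <- function(p, n, seed = 1) {
  set.seed(seed)
  abundance_matrix(
    matrix(rnorm(p * n, 20, 1), p, n,
           dimnames = list(sprintf("P%03d", seq_len(p)),
                           sprintf("s%02d", seq_len(n)))),
    scale = "log2")
}

# default design used across tests: 6 stages x 3 reps
default_design <- function() generate_design()
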