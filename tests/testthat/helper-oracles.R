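# Independent brute-force oracles used across the suite. None of these
# call the code paths they check.

# Floyd-Warshall all-pairs shortest hop counts on a 0/1 adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

fw_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# Average ranks computed from scratch (no rank()).
brute_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman as Pearson on brute-force average ranks, Pearson from the
# explicit covariance formula.
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_spearman <- function(x, y) {
  brute_pearson(brute_ranks(x), brute_ranks(y))
}

# Benjamini-Hochberg step-up by definition: largest k with
# p_(k) <= q * k / m; reject all hypotheses with p <= p_(k).
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  k <- max(c(0, which(sorted <= q * seq_len(m) / m)))
  if (k == 0) return(rep(FALSE, m))
  p <= sorted[k]
}

# Partial F for the last block of columns via explicit normal equations.
brute_partial_f <- function(y, x_reduced, x_extra) {
  sse <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  x_full <- cbind(x_reduced, x_extra)
  sse_r <- sse(x_reduced)
  sse_f <- sse(x_full)
  df_diff <- ncol(x_full) - ncol(x_reduced)
  df_f <- length(y) - ncol(x_full)
  ((sse_r - sse_f) / df_diff) / (sse_f / df_f)
}

random_graph <- function(n, p_edge) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p_edge)
  a + t(a)
}

# Small cohort for pipeline-level tests: full 90-node atlas, few subjects.
tiny_cohort_config <- function(n = c("TDC" = 5, "ADHD-I" = 5, "ADHD-C" = 5),
                               seed = 101, ...) {
  cohort_config(n_per_group = n, seed = seed, ...)
}
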