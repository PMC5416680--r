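# Independent brute-force oracles used to check the implementation. These
# deliberately avoid the package's own code paths.

# NB pmf from its closed form (log scale), not via dnbinom.
oracle_nb_pmf <- function(k, mu, size) {
  exp(lgamma(k + size) - lgamma(size) - lfactorial(k) +
        size * (log(size) - log(size + mu)) +
        k * (log(mu) - log(mu + size)))
}

# Conditional exact test by explicit enumeration of every partition of S.
oracle_exact_p <- function(k_a, k_b, s_a, s_b, alpha) {
  S <- k_a + k_b
  if (S == 0) return(1)
  q <- S / sum(c(s_a, s_b))
  mu_a <- q * sum(s_a); mu_b <- q * sum(s_b)
  size_a <- sum(s_a)^2 / (alpha * sum(s_a^2))
  size_b <- sum(s_b)^2 / (alpha * sum(s_b^2))
  f <- sapply(0:S, function(a)
    oracle_nb_pmf(a, mu_a, size_a) * oracle_nb_pmf(S - a, mu_b, size_b))
  min(1, sum(f[f <= f[k_a + 1] * (1 + 1e-7)]) / sum(f))
}

# BH by the literal step-up definition on the sorted vector.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in m:1) {
    v <- m / i * sorted[i]
    adj[i] <- if (i == m) min(1, v) else min(adj[i + 1], v)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by direct binomial-coefficient summation.
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Two-sample KS D by scanning the pooled value grid.
oracle_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(sapply(grid, function(v) mean(x <= v) - mean(y <= v))))
}

# Seed expansion + induced edges, built purely with set operations on an
# edge data.frame.
oracle_pin <- function(edges, seeds) {
  nb <- unique(c(edges$b[edges$a %in% seeds], edges$a[edges$b %in% seeds]))
  nodes <- union(intersect(seeds, unique(c(edges$a, edges$b))), nb)
  keep <- edges$a %in% nodes & edges$b %in% nodes
  list(nodes = sort(nodes),
       edges = edges[keep, , drop = FALSE])
}

# Small planted qPCR-plate-free fixtures used across files.
tiny_counts <- function() {
  m <- matrix(c(0L, 5L, 3L, 7L), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  count_matrix(m, c(s1 = "case", s2 = "control"))
}
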