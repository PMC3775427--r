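# Brute-force reference implementations, independent of the package's code
# paths: Floyd-Warshall distances, triple-scan triangle counts, the raw
# double-sum modularity formula, and concordant/discordant pair counting.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) t_i <- t_i + 1
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  ci
}

bf_modularity <- function(adj, mem) {
  n <- nrow(adj)
  k <- rowSums(adj)
  m <- sum(adj) / 2
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mem[i] == mem[j]) q <- q + adj[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

bf_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Random test graphs / matrices ------------------------------------------

random_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    adj <- matrix(0L, n, n)
    up <- upper.tri(adj)
    adj[up] <- as.integer(runif(sum(up)) < p)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    binary_graph(adj)
  })
}

random_weight_matrix <- function(n, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    connectivity_matrix(w)
  })
}

# Adjusted Rand index, for partition-recovery checks.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
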