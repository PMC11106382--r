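# Brute-force graph-metric oracles, independent of the igraph-backed
# implementation: Floyd-Warshall distances, DP shortest-path counting for
# betweenness, direct triangle counting. Intended for graphs with N <= 12.

bf_distances <- function(adj) {
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

# number of shortest paths between every pair, by dynamic programming in
# order of increasing distance from the source
bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (u in which(d[s, ] == dist)) {
        pred <- which(adj[, u] != 0 & d[s, ] == dist - 1)
        nsp[s, u] <- sum(nsp[s, pred])
      }
    }
  }
  nsp
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  nsp <- bf_path_counts(adj, d)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  bc
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  list(node = vals, mean = mean(vals))
}

bf_lp <- function(adj) {
  d <- bf_distances(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bf_eglob <- function(adj) {
  d <- bf_distances(adj)
  off <- d[row(d) != col(d)]
  mean(1 / off)
}

bf_eloc <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    bf_eglob(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

bf_nodal_efficiency <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# step-up BH by explicit scan over all rank cutoffs
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    adj[i] <- min(1, min(p[ord][rank_i:m] * m / (rank_i:m)))
  }
  adj
}

random_adjacency <- function(n, p_edge = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p_edge)
  a + t(a)
}

adjacency_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}
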