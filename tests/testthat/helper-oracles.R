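# Independent brute-force oracles for the graph metrics. Deliberately naive:
# Floyd-Warshall distances with path counting, exhaustive triple enumeration
# for clustering, per-node subgraph recomputation for local efficiency.
# Nothing here shares code with the package implementations.

bf_lengths <- function(adj) {
  len <- 1 / adj
  len[adj == 0] <- Inf
  diag(len) <- 0
  len
}

# Floyd-Warshall all-pairs shortest path lengths + path counts
bf_shortest <- function(adj, tol = 1e-12) {
  n <- nrow(adj)
  d <- bf_lengths(adj)
  sigma <- matrix(0, n, n)
  sigma[is.finite(d) & d > 0] <- 1
  diag(sigma) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        alt <- d[i, k] + d[k, j]
        if (k == i || k == j || !is.finite(alt)) next
        if (alt < d[i, j] - tol) {
          d[i, j] <- alt
          sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (abs(alt - d[i, j]) <= tol) {
          sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
      }
    }
  }
  list(d = d, sigma = sigma)
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_shortest(adj)$d
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

bf_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_shortest(adj)$d
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

bf_lp <- function(adj) {
  d <- bf_shortest(adj)$d
  diag(d) <- NA
  reach <- is.finite(d) & !is.na(d)
  if (!any(reach)) NA_real_ else mean(d[reach])
}

# Onnela weighted clustering by exhaustive triple enumeration
bf_clustering <- function(adj) {
  n <- nrow(adj)
  w <- adj / max(adj)
  k <- rowSums(adj > 0)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        acc <- acc + (w[i, j] * w[j, h] * w[i, h])^(1 / 3)
      }
    }
    nodal[i] <- acc / (k[i] * (k[i] - 1))
  }
  list(cp = mean(nodal), nodal = nodal)
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(adj[i, ] > 0)
    if (length(nbrs) >= 2) {
      nodal[i] <- bf_global_efficiency(adj[nbrs, nbrs, drop = FALSE])
    }
  }
  list(e_loc = mean(nodal), nodal = nodal)
}

# betweenness via pair-dependency formula delta_st(v) =
# sigma_sv * sigma_vt / sigma_st when d_sv + d_vt == d_st (endpoints excluded)
bf_betweenness <- function(adj, tol = 1e-12) {
  n <- nrow(adj)
  sp <- bf_shortest(adj, tol)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t || !is.finite(sp$d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(sp$d[s, v]) && is.finite(sp$d[v, t]) &&
            abs(sp$d[s, v] + sp$d[v, t] - sp$d[s, t]) <= tol) {
          bc[v] <- bc[v] + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
        }
      }
    }
  }
  bc
}

# exact-summation Gaussian KDE (independent of the package's binned path)
bf_kde <- function(x, h, grid) {
  vapply(grid, function(g) mean(dnorm((g - x) / h)) / h, numeric(1))
}

# random symmetric weighted adjacency with given edge density
random_adjacency <- function(n, density, weighted = TRUE) {
  adj <- matrix(0, n, n)
  ut <- which(upper.tri(adj))
  keep <- ut[runif(length(ut)) < density]
  adj[keep] <- if (weighted) runif(length(keep), 0.1, 1) else 1
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}
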