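#' Clustering coefficient (binary or Onnela-weighted)
#'
#' Binary graphs use the classical `C_i = 2 t_i / (k_i (k_i - 1))`; weighted
#' graphs use the Onnela geometric-mean form on weights normalized by the
#' graph maximum. Nodes with fewer than two neighbors contribute 0, and the
#' network value is the mean over all nodes.
#'
#' @param g a `thresholded_graph`.
#' @return list with `cp` (network mean) and `nodal` (per-node vector).
#' @export
clustering_coefficient <- function(g) {
  a <- g$adjacency
  k <- rowSums(a > 0)
  wmax <- max(a)
  if (wmax == 0) {
    return(list(cp = 0, nodal = setNames(rep(0, g$n_nodes), rownames(a))))
  }
  w <- (a / wmax)^(1 / 3)
  t3 <- diag(w %*% w %*% w)
  nodal <- ifelse(k < 2, 0, t3 / (k * (k - 1)))
  list(cp = mean(nodal), nodal = setNames(nodal, rownames(a)))
}

#' Characteristic path length, global and nodal efficiency
#'
#' Shortest paths are computed on edge lengths `1/weight` (1 for binary
#' edges). Global efficiency averages `1/d_ij` over all ordered pairs with
#' unreachable pairs contributing 0; nodal efficiency does the same per node.
#' The characteristic path length averages `d_ij` over *reachable* pairs
#' only, and a `disconnected` flag reports whether any pair was unreachable.
#'
#' @param g a `thresholded_graph`.
#' @return list with `lp`, `e_glob`, `nodal_efficiency`, `disconnected`, and
#'   `reachable_fraction` of ordered pairs.
#' @export
path_and_efficiency <- function(g) {
  ig <- tg_igraph(g)
  d <- igraph::distances(ig, weights = tg_lengths(ig))
  diag(d) <- NA
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  n <- g$n_nodes
  off <- !is.na(d)
  reach <- is.finite(d) & off
  list(
    lp = if (any(reach)) mean(d[reach]) else NA_real_,
    e_glob = sum(inv, na.rm = TRUE) / (n * (n - 1)),
    nodal_efficiency = setNames(rowSums(inv, na.rm = TRUE) / (n - 1),
                                rownames(g$adjacency)),
    disconnected = any(!reach & off),
    reachable_fraction = sum(reach) / (n * (n - 1)))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (edge weights inherited); nodes with fewer than two neighbors
#' score 0. The network value is the mean over nodes.
#'
#' @param g a `thresholded_graph`.
#' @return list with `e_loc` and per-node `nodal`.
#' @export
local_efficiency <- function(g) {
  a <- g$adjacency
  nodal <- vapply(seq_len(g$n_nodes), function(i) {
    nbrs <- which(a[i, ] > 0)
    if (length(nbrs) < 2) return(0)
    sub <- as_thresholded_graph(a[nbrs, nbrs, drop = FALSE], g$mode)
    path_and_efficiency(sub)$e_glob
  }, numeric(1))
  list(e_loc = mean(nodal), nodal = setNames(nodal, rownames(a)))
}

#' Nodal betweenness centrality
#'
#' Shortest-path betweenness on `1/weight` edge lengths with fractional
#' splitting across equal-length paths; endpoints are excluded.
#'
#' @param g a `thresholded_graph`.
#' @return per-node numeric vector.
#' @export
node_betweenness <- function(g) {
  ig <- tg_igraph(g)
  setNames(igraph::betweenness(ig, weights = tg_lengths(ig), directed = FALSE),
           rownames(g$adjacency))
}

#' Nodal degree (binary count or weighted strength)
#'
#' @param g a `thresholded_graph`.
#' @return per-node numeric vector: neighbor count in binary mode, sum of
#'   incident weights in weighted mode.
#' @export
nodal_degree <- function(g) {
  a <- g$adjacency
  v <- if (g$mode == "binary") rowSums(a > 0) else rowSums(a)
  setNames(v, rownames(a))
}

#' Small-world indices against degree-preserving null networks
#'
#' Generates `n_null` Maslov-Sneppen rewired graphs (double-edge swaps, the
#' binary degree sequence preserved exactly; in weighted mode the multiset of
#' edge weights is reassigned randomly to the rewired topology), then
#' normalizes: `gamma = Cp / <Cp_null>`, `lambda = Lp / <Lp_null>`,
#' `sigma = gamma / lambda`. Deterministic under `set.seed()` / `seed`.
#'
#' @param g a `thresholded_graph` with at least 95% of node pairs reachable.
#' @param n_null number of null networks (default 100).
#' @param n_swaps_per_edge accepted swaps per edge (default 10).
#' @param seed optional RNG seed.
#' @return list with `gamma`, `lambda`, `sigma`, the observed `cp`/`lp`, and
#'   the null ensembles `cp_null`/`lp_null`.
#' @export
small_world_indices <- function(g, n_null = 100L, n_swaps_per_edge = 10L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pe <- path_and_efficiency(g)
  if (pe$reachable_fraction < 0.95) {
    stop_morphnet(
      "graph too disconnected for small-world indices (%.1f%% pairs reachable)",
      100 * pe$reachable_fraction, class = "morphnet_disconnected")
  }
  cp_obs <- clustering_coefficient(g)$cp
  a <- g$adjacency
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  weights <- a[idx]
  e <- nrow(idx)
  target <- as.integer(n_swaps_per_edge) * e
  cp_null <- lp_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    res <- .double_edge_swap_cpp(cbind(idx[, 1] - 1L, idx[, 2] - 1L),
                                 g$n_nodes, target, 1000L * target)
    if (res$accepted < target) {
      stop_morphnet(
        "degree-preserving rewiring failed: %d/%d swaps accepted (ratio %.3f)",
        res$accepted, target, res$accepted / res$tries,
        class = "morphnet_rewire_failure")
    }
    enew <- res$edges + 1L
    anull <- matrix(0, g$n_nodes, g$n_nodes)
    w <- if (g$mode == "binary") rep(1, e) else sample(weights)
    anull[enew] <- w
    anull[enew[, 2:1, drop = FALSE]] <- w
    gn <- structure(list(adjacency = anull, n_nodes = g$n_nodes,
                         n_edges = e, sparsity = g$sparsity, mode = g$mode),
                    class = "thresholded_graph")
    cp_null[b] <- clustering_coefficient(gn)$cp
    lp_null[b] <- path_and_efficiency(gn)$lp
  }
  gamma <- cp_obs / mean(cp_null)
  lambda <- pe$lp / mean(lp_null)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = cp_obs, lp = pe$lp, cp_null = cp_null, lp_null = lp_null)
}
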