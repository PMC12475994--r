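#' Sparsity threshold grid
#'
#' Default grid: sparsity 0.10 to 0.34 in steps of 0.01 (25 thresholds),
#' the conventional range over which morphological networks are summarized.
#'
#' @param s_min,s_max,step grid limits and spacing.
#' @return a `sparsity_grid` with a `thresholds` field.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_min < s_max && s_max <= 1 && step > 0)) {
    stop_morphnet("require 0 < s_min < s_max <= 1 and step > 0",
                  class = "morphnet_config_error")
  }
  n <- round((s_max - s_min) / step) + 1L
  structure(list(s_min = s_min, s_max = s_max, step = step,
                 thresholds = s_min + step * (seq_len(n) - 1L)),
            class = "sparsity_grid")
}

#' Threshold a similarity matrix at a target sparsity
#'
#' Retains exactly `round_half_up(s * N(N-1)/2)` strongest off-diagonal
#' edges. Ties at the weight cutoff are broken deterministically by ascending
#' `(i, j)` lexicographic order. `mode = "weighted"` keeps the original
#' similarity weights; `mode = "binary"` sets retained edges to 1.
#'
#' @param m symmetric similarity matrix (a [build_network()] result or plain
#'   matrix).
#' @param s target sparsity in `(0, 1]`.
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return a `thresholded_graph`: list with `adjacency` (symmetric matrix),
#'   `n_nodes`, `n_edges`, `sparsity`, `mode`.
#' @export
threshold_at_sparsity <- function(m, s, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  m <- unclass(m)
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  if (!(s > 0 && s <= 1)) {
    stop_morphnet("sparsity must be in (0, 1]", class = "morphnet_config_error")
  }
  tg_from_ranking(edge_ranking(m), s, mode, dimnames(m))
}

# descending-weight edge order with the deterministic (i, j) tie-break;
# computed once and shared across a whole sparsity grid
edge_ranking <- function(m) {
  n <- nrow(m)
  ut <- upper.tri(m)
  ii <- row(m)[ut]
  jj <- col(m)[ut]
  ww <- m[ut]
  ord <- order(-ww, ii, jj)
  list(i = ii[ord], j = jj[ord], w = ww[ord], n = n)
}

tg_from_ranking <- function(rk, s, mode, dn = NULL) {
  n <- rk$n
  e_target <- round_half_up(s * n * (n - 1) / 2)
  if (e_target < 1) {
    stop_morphnet("sparsity %g retains no edges on %d nodes", s, n,
                  class = "morphnet_empty_graph")
  }
  sel <- seq_len(e_target)
  adj <- matrix(0, n, n, dimnames = dn)
  vals <- if (mode == "binary") 1 else rk$w[sel]
  adj[cbind(rk$i[sel], rk$j[sel])] <- vals
  adj[cbind(rk$j[sel], rk$i[sel])] <- vals
  structure(list(adjacency = adj, n_nodes = n, n_edges = e_target,
                 sparsity = s, mode = mode),
            class = "thresholded_graph")
}

#' Wrap an adjacency matrix as a thresholded graph
#'
#' Mostly useful for tests and for metrics on hand-built graphs.
#'
#' @param adj symmetric non-negative adjacency matrix, zero diagonal.
#' @param mode `"weighted"` or `"binary"`.
#' @export
as_thresholded_graph <- function(adj, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  adj <- unclass(adj)
  if (max(abs(adj - t(adj))) > 1e-12 || any(diag(adj) != 0)) {
    stop_morphnet("adjacency must be symmetric with zero diagonal",
                  class = "morphnet_config_error")
  }
  structure(list(adjacency = adj, n_nodes = nrow(adj),
                 n_edges = sum(adj[upper.tri(adj)] > 0),
                 sparsity = mean(adj[upper.tri(adj)] > 0), mode = mode),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (S = %.3f, %s)\n",
              x$n_nodes, x$n_edges, x$sparsity, x$mode))
  invisible(x)
}

tg_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      weighted = TRUE)
}

# igraph edge lengths: shortest paths run on 1/weight (binary weights are 1)
tg_lengths <- function(ig) {
  w <- igraph::E(ig)$weight
  if (is.null(w)) rep(1, igraph::ecount(ig)) else 1 / w
}
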