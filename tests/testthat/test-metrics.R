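k5 <- function(mode = "binary") {
  adj <- matrix(1, 5, 5) - diag(5)
  as_thresholded_graph(adj, mode)
}

star5 <- function() {
  adj <- matrix(0, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- 1
  as_thresholded_graph(adj, "binary")
}

cycle6 <- function() {
  adj <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    adj[i, j] <- adj[j, i] <- 1
  }
  as_thresholded_graph(adj, "binary")
}

test_that("closed-form values on canonical graphs", {
  expect_equal(clustering_coefficient(k5())$cp, 1)
  expect_equal(clustering_coefficient(cycle6())$cp, 0)
  pe <- path_and_efficiency(k5())
  expect_equal(pe$lp, 1)
  expect_equal(pe$e_glob, 1)
  expect_false(pe$disconnected)
  # 5-node star: 8 ordered pairs at d=1, 12 at d=2
  expect_equal(path_and_efficiency(star5())$e_glob, 0.7)
  # 6-cycle: per-node distances 1,2,3,2,1
  expect_equal(path_and_efficiency(cycle6())$lp, 1.8)
  expect_equal(local_efficiency(k5())$e_loc, 1)
  expect_equal(local_efficiency(star5())$e_loc, 0)
  bc <- node_betweenness(star5())
  expect_equal(unname(bc), c(6, 0, 0, 0, 0))
  path3 <- as_thresholded_graph(
    rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)), "binary")
  expect_equal(unname(node_betweenness(path3)), c(0, 1, 0))
  expect_equal(unname(nodal_degree(k5())), rep(4, 5))
})

test_that("degree obeys the handshake identity; weighted degree sums weights", {
  adj <- matrix(0, 6, 6)
  adj[1, 2] <- adj[2, 1] <- 0.7
  g <- as_thresholded_graph(adj, "weighted")
  expect_equal(unname(nodal_degree(g)), c(0.7, 0.7, 0, 0, 0, 0))
  set.seed(5)
  for (rep in 1:5) {
    a <- random_adjacency(8, 0.5)
    g <- as_thresholded_graph(a, "weighted")
    expect_equal(sum(nodal_degree(g)), 2 * sum(a[upper.tri(a)]),
                 tolerance = 1e-12)
  }
})

test_that("weighted metrics match brute-force oracles on random graphs", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    adj <- random_adjacency(n, runif(1, 0.4, 0.9))
    g <- as_thresholded_graph(adj, "weighted")
    cc <- clustering_coefficient(g)
    oc <- bf_clustering(adj)
    expect_equal(unname(cc$nodal), oc$nodal, tolerance = 1e-12)
    pe <- path_and_efficiency(g)
    expect_equal(pe$e_glob, bf_global_efficiency(adj), tolerance = 1e-10)
    expect_equal(unname(pe$nodal_efficiency), bf_nodal_efficiency(adj),
                 tolerance = 1e-10)
    expect_equal(pe$lp, bf_lp(adj), tolerance = 1e-10)
    expect_equal(unname(local_efficiency(g)$nodal),
                 bf_local_efficiency(adj)$nodal, tolerance = 1e-10)
    expect_equal(unname(node_betweenness(g)), bf_betweenness(adj),
                 tolerance = 1e-8)
  }
})

test_that("binary and weighted modes agree on 0/1 matrices", {
  set.seed(7)
  for (rep in 1:5) {
    adj <- random_adjacency(9, 0.5, weighted = FALSE)
    gb <- as_thresholded_graph(adj, "binary")
    gw <- as_thresholded_graph(adj, "weighted")
    expect_equal(clustering_coefficient(gb)$nodal,
                 clustering_coefficient(gw)$nodal, tolerance = 1e-12)
    expect_equal(path_and_efficiency(gb)$e_glob,
                 path_and_efficiency(gw)$e_glob, tolerance = 1e-12)
    expect_equal(nodal_degree(gb), nodal_degree(gw), tolerance = 1e-12)
    expect_equal(node_betweenness(gb), node_betweenness(gw),
                 tolerance = 1e-10)
  }
})

test_that("null models preserve the degree sequence and seeds reproduce", {
  set.seed(8)
  adj <- ring_lattice(30, k = 4, p_rewire = 0.1, seed = 3)
  g <- as_thresholded_graph(adj, "binary")
  sw1 <- small_world_indices(g, n_null = 10, seed = 99)
  sw2 <- small_world_indices(g, n_null = 10, seed = 99)
  expect_identical(sw1, sw2)
  # degree preservation: rerun one swap sequence directly
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  set.seed(1)
  res <- morphnet:::.double_edge_swap_cpp(cbind(idx[, 1] - 1L, idx[, 2] - 1L),
                                          30L, 10L * nrow(idx),
                                          1000L * nrow(idx))
  anull <- matrix(0, 30, 30)
  anull[res$edges + 1L] <- 1
  anull[res$edges[, 2:1] + 1L] <- 1
  expect_identical(rowSums(anull), rowSums(adj))
  expect_false(identical(anull, adj))
})

test_that("weighted-mode small-world indices are finite on a dense graph", {
  set.seed(9)
  m <- random_adjacency(24, 1)
  g <- threshold_at_sparsity(m, 0.35, mode = "weighted")
  sw <- small_world_indices(g, n_null = 5, seed = 4)
  expect_true(all(is.finite(c(sw$gamma, sw$lambda, sw$sigma))))
  expect_gt(sw$gamma, 0)
})

test_that("E_glob and edge count are non-decreasing in sparsity", {
  set.seed(10)
  m <- random_adjacency(30, 1)
  grid <- sparsity_grid(0.1, 0.5, 0.05)
  eg <- vapply(grid$thresholds, function(s) {
    path_and_efficiency(threshold_at_sparsity(m, s))$e_glob
  }, numeric(1))
  ec <- vapply(grid$thresholds, function(s) {
    threshold_at_sparsity(m, s)$n_edges
  }, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
  expect_true(all(diff(ec) >= 0))
})

test_that("metric_curves assembles curves and trapezoidal AUCs", {
  s <- tiny_subject(n_rois = 15, n = 100, seed = 11)
  m <- build_network(s)
  grid <- sparsity_grid(0.2, 0.4, 0.05)
  mc <- metric_curves(m, grid, global_metrics = c("cp", "e_glob"),
                      nodal_metrics = "degree")
  expect_identical(nrow(mc$global), 5L)
  width <- 0.4 - 0.2
  # constant curve c integrates to width * c; check against direct trapezoid
  direct <- sum((mc$global$cp[-1] + mc$global$cp[-5]) / 2) * 0.05
  expect_equal(mc$auc_global[["cp"]], direct, tolerance = 1e-12)
  expect_identical(dim(mc$nodal$degree), c(15L, 5L))
  expect_length(mc$auc_nodal$degree, 15L)
  # rectangle/trapezoid identities
  expect_equal(morphnet:::trapz_auc(seq(0.1, 0.34, 0.01), rep(3, 25)),
               0.24 * 3, tolerance = 1e-12)
  lin <- seq(2, 5, length.out = 25)
  expect_equal(morphnet:::trapz_auc(seq(0.1, 0.34, 0.01), lin),
               0.24 * (2 + 5) / 2, tolerance = 1e-12)
})

test_that("curve errors carry the offending threshold", {
  s <- tiny_subject(n_rois = 6, n = 80, seed = 12)
  m <- build_network(s)
  err <- expect_error(
    metric_curves(m, sparsity_grid(0.01, 0.05, 0.01),
                  global_metrics = "cp", nodal_metrics = "degree"),
    class = "morphnet_empty_graph")
  expect_match(conditionMessage(err), "sparsity 0.01")
})
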