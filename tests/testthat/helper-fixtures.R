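# Shared fixtures: deliberately small cohorts/subjects so unit tests stay fast.

tiny_config <- function(seed = 7L, ...) {
  defaults <- list(group_sizes = c(HC = 4L, DM = 4L, DKD = 4L),
                   n_rois = 12L, voxels_per_roi = c(60L, 120L),
                   affected_rois = c(2L, 5L, 9L),
                   effect_grades = c(HC = 0, DM = 0.3, DKD = 0.6),
                   seed = seed)
  do.call(cohort_config, modifyList(defaults, list(...)))
}

tiny_subject <- function(n_rois = 8, n = 200, seed = 1) {
  set.seed(seed)
  vals <- lapply(seq_len(n_rois), function(i) {
    rlnorm(n, log(0.5) + 0.05 * i, 0.3)
  })
  names(vals) <- paste0("R", seq_len(n_rois))
  roi_sample_set(vals, "tiny", "toy")
}

# ring lattice on n nodes, each connected to k/2 neighbors per side, with a
# fraction of edges randomly rewired (classic small-world construction)
ring_lattice <- function(n, k = 6, p_rewire = 0, seed = 1) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  if (p_rewire > 0) {
    ut <- which(upper.tri(adj) & adj > 0)
    rew <- ut[runif(length(ut)) < p_rewire]
    for (e in rew) {
      i <- row(adj)[e]
      free <- which(adj[i, ] == 0 & seq_len(n) != i)
      if (!length(free)) next
      j2 <- free[sample.int(length(free), 1)]
      adj[e] <- 0
      adj[col(adj)[e], i] <- 0
      adj[i, j2] <- adj[j2, i] <- 1
    }
  }
  adj
}
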