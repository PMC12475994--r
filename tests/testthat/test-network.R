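test_that("matrix entries agree with the composed single-pair operations", {
  s <- tiny_subject(n_rois = 5, n = 150, seed = 2)
  m <- build_network(s)
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    i <- pair[1]; j <- pair[2]
    xi <- s$samples[[i]]; xj <- s$samples[[j]]
    hi <- morphnet:::kde_bandwidth(xi)
    hj <- morphnet:::kde_bandwidth(xj)
    h <- max(hi, hj)
    grid <- seq(min(xi, xj) - 3 * h, max(xi, xj) + 3 * h, length.out = 128)
    pi <- estimate_pdf(xi, grid = grid)
    # force ROI j's own bandwidth on the shared grid
    dj <- morphnet:::.kde_grid_cpp(xj, hj, grid[1], grid[128], 128L)
    d <- symmetrized_kld(pi$density, dj)
    expect_equal(m[i, j], kld_to_similarity(d), tolerance = 1e-12)
  }
})

test_that("similarity matrices are symmetric with entries in (0, 1]", {
  s <- tiny_subject(n_rois = 10, n = 120, seed = 3)
  m <- build_network(s)
  expect_identical(dim(unclass(m)), c(10L, 10L))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 0))
  offd <- m[upper.tri(m)]
  expect_true(all(offd > 0 & offd <= 1))
})

test_that("identical ROI vectors give similarity ~1, distant ones ~0", {
  set.seed(5)
  x <- rlnorm(400, 0, 0.3)
  s <- roi_sample_set(list(A = x, B = x, C = rlnorm(400, 0, 0.3)), "dup")
  m <- build_network(s)
  expect_gte(m["A", "B"], 0.999)
  # N(0,1) vs N(5,1): closed-form symmetrized Gaussian KL = 25, so the
  # similarity must collapse
  sep <- roi_sample_set(list(P = rnorm(2000) + 10, Q = rnorm(2000, 15)),
                        "sep", min_voxels = 10)
  m2 <- build_network(sep)
  expect_lt(m2["P", "Q"], 0.01)
})

test_that("permuting ROI order permutes rows and columns identically", {
  s <- tiny_subject(n_rois = 7, n = 100, seed = 8)
  m <- build_network(s)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  sp <- roi_sample_set(s$samples[perm], s$subject_id, s$atlas_name)
  mp <- build_network(sp)
  expect_equal(unclass(mp), unclass(m)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("similarities are invariant to a global rescaling of the data", {
  s <- tiny_subject(n_rois = 6, n = 150, seed = 9)
  m1 <- build_network(s)
  s2 <- roi_sample_set(lapply(s$samples, function(v) v * 7.3),
                       s$subject_id, s$atlas_name)
  m2 <- build_network(s2)
  expect_lt(max(abs(unclass(m1) - unclass(m2))), 1e-3)
})

test_that("disjoint half-samples give stable similarities", {
  set.seed(12)
  rois <- lapply(1:4, function(i) rlnorm(2000, 0.05 * i, 0.35))
  names(rois) <- paste0("R", 1:4)
  half1 <- roi_sample_set(lapply(rois, function(v) v[1:1000]), "h1")
  half2 <- roi_sample_set(lapply(rois, function(v) v[1001:2000]), "h2")
  m1 <- build_network(half1)
  m2 <- build_network(half2)
  expect_lt(max(abs(unclass(m1) - unclass(m2))), 0.1)
})

test_that("degenerate ROIs abort with the ROI named", {
  s <- list(A = rlnorm(50, 0, .2), B = rep(2, 50))
  err <- expect_error(build_network(roi_sample_set(s, "bad")),
                      class = "morphnet_degenerate_roi")
  expect_match(conditionMessage(err), "B")
})

test_that("similarity TSV round-trips", {
  s <- tiny_subject(n_rois = 5, n = 80, seed = 1)
  m <- build_network(s)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(m, p)
  back <- read_similarity(p, subject_id = "tiny")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(m))
})
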