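#' Gaussian kernel density estimate on a uniform grid
#'
#' Estimates the probability density function of a vector of gray-matter
#' values on a uniform evaluation grid. The default bandwidth is the
#' Silverman rule-of-thumb `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`; when the
#' IQR collapses to zero with positive variance, the sd term alone is used.
#' Density evaluation uses linear binning on the grid followed by exact
#' Gaussian kernel convolution — the same code path used by
#' [build_network()], so composing the two gives identical numbers.
#'
#' @param values numeric vector of finite values, length at least
#'   `min_voxels`, with positive variance.
#' @param grid uniform, strictly increasing evaluation points; defaults to
#'   `grid_size` points spanning the sample range extended by 3 bandwidths.
#' @param bandwidth_rule `"silverman"` (default, factor 0.9) or `"scott"`
#'   (factor 1.06).
#' @param grid_size number of grid points when `grid` is not supplied.
#' @param min_voxels minimum sample size.
#' @return a `density_estimate` with fields `grid`, `density`, `bandwidth`
#'   and the trapezoidal `integral` of the density over the grid.
#' @export
estimate_pdf <- function(values, grid = NULL, bandwidth_rule = "silverman",
                         grid_size = 128L, min_voxels = 10L) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_morphnet("values must be finite numerics",
                  class = "morphnet_value_error")
  }
  if (length(values) < min_voxels) {
    stop_morphnet("need at least %d values, got %d", min_voxels,
                  length(values), class = "morphnet_degenerate_roi")
  }
  h <- kde_bandwidth(values, bandwidth_rule)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h,
                length.out = grid_size)
  }
  dg <- diff(grid)
  if (length(grid) < 8L || any(dg <= 0) ||
      max(abs(dg - dg[1])) > 1e-8 * dg[1]) {
    stop_morphnet("grid must be uniform and strictly increasing",
                  class = "morphnet_config_error")
  }
  dens <- .kde_grid_cpp(as.double(values), h, grid[1], grid[length(grid)],
                        length(grid))
  structure(list(grid = grid, density = dens, bandwidth = h,
                 integral = trapz_auc(grid, dens)),
            class = "density_estimate")
}

kde_bandwidth <- function(values, bandwidth_rule = "silverman") {
  s <- sd(values)
  if (!is.finite(s) || s <= 0) {
    stop_morphnet("degenerate distribution: sample variance is zero",
                  class = "morphnet_degenerate_distribution")
  }
  iqr <- IQR(values) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  factor <- switch(bandwidth_rule,
    silverman = 0.9,
    scott = 1.06,
    stop_morphnet("unknown bandwidth_rule '%s'", bandwidth_rule,
                  class = "morphnet_config_error"))
  factor * spread * length(values)^(-1 / 5)
}

#' Symmetrized Kullback-Leibler divergence between two density estimates
#'
#' Discretizes both densities to probability masses on their shared grid
#' (an epsilon floor is added before renormalization to keep the divergence
#' finite) and returns `KL(P||Q) + KL(Q||P)` in nats. Bare numeric vectors
#' are accepted as already-discretized masses on a common support, which is
#' convenient for worked examples and testing.
#'
#' @param p,q `density_estimate` objects sharing an identical grid, or bare
#'   non-negative numeric vectors of equal length.
#' @param eps floor added to each mass before renormalization.
#' @return non-negative divergence in nats.
#' @export
symmetrized_kld <- function(p, q, eps = 1e-12) {
  if (inherits(p, "density_estimate") && inherits(q, "density_estimate")) {
    if (length(p$grid) != length(q$grid) ||
        max(abs(p$grid - q$grid)) > 1e-9) {
      stop_morphnet("density estimates must share an identical grid",
                    class = "morphnet_grid_mismatch")
    }
    p <- p$density
    q <- q$density
  }
  if (!is.numeric(p) || !is.numeric(q) || length(p) != length(q)) {
    stop_morphnet("p and q must be numeric vectors of equal length",
                  class = "morphnet_grid_mismatch")
  }
  if (any(p < 0) || any(q < 0)) {
    stop_morphnet("densities must be non-negative",
                  class = "morphnet_value_error")
  }
  .sym_kl_cpp(as.double(p), as.double(q), eps)
}

#' Map a divergence to an edge similarity in (0, 1]
#'
#' Uses `exp(-d)`: strictly decreasing, equal to 1 iff the divergence is 0.
#'
#' @param d non-negative divergence (vectorized).
#' @return similarity values in `(0, 1]`.
#' @export
kld_to_similarity <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_morphnet("divergence must be finite and non-negative",
                  class = "morphnet_value_error")
  }
  exp(-d)
}
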