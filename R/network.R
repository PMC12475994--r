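#' Build a subject's morphological similarity network
#'
#' Turns one subject's per-ROI value vectors into a symmetric N x N
#' similarity-weighted connectivity matrix. For each unordered ROI pair the
#' two kernel density estimates are evaluated on one shared uniform grid
#' spanning the pooled sample range extended by 3 pooled bandwidths
#' (`max(h_i, h_j)`), the symmetrized Kullback-Leibler divergence between the
#' discretized distributions is computed, and the edge weight is
#' `exp(-divergence)`, giving similarities in `(0, 1]`. The diagonal is fixed
#' to 0 (no self-loops).
#'
#' @param s a [roi_sample_set()].
#' @param grid_size number of shared-grid evaluation points per pair
#'   (default 128).
#' @param bandwidth_rule bandwidth rule passed to the KDE (see
#'   [estimate_pdf()]).
#' @param eps mass floor used in the divergence (see [symmetrized_kld()]).
#' @return a `similarity_matrix`: an N x N symmetric numeric matrix with ROI
#'   dimnames and attributes `subject_id`, `atlas_name` and `settings`.
#' @export
build_network <- function(s, grid_size = 128L, bandwidth_rule = "silverman",
                          eps = 1e-12) {
  stopifnot(inherits(s, "roi_sample_set"))
  bw <- vapply(seq_along(s$samples), function(i) {
    tryCatch(kde_bandwidth(s$samples[[i]], bandwidth_rule),
             morphnet_degenerate_distribution = function(e) {
               stop_morphnet("ROI %s: %s", names(s$samples)[i],
                             conditionMessage(e),
                             class = "morphnet_degenerate_roi")
             })
  }, numeric(1))
  m <- .similarity_matrix_cpp(lapply(s$samples, as.double), bw,
                              as.integer(grid_size), eps)
  dimnames(m) <- list(names(s$samples), names(s$samples))
  structure(m, class = c("similarity_matrix", "matrix", "array"),
            subject_id = s$subject_id, atlas_name = s$atlas_name,
            settings = list(grid_size = as.integer(grid_size),
                            bandwidth_rule = bandwidth_rule, eps = eps,
                            similarity = "exp(-symmetrized KLD)"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  offd <- x[upper.tri(x)]
  cat(sprintf(
    "<similarity_matrix> subject %s, %d nodes, weights in [%.3f, %.3f]\n",
    attr(x, "subject_id") %||% "?", nrow(x), min(offd), max(offd)))
  invisible(x)
}

#' Write / read a similarity matrix as headered TSV
#'
#' @param m a `similarity_matrix` (or plain symmetric matrix).
#' @param path TSV path; ROI labels form the header.
#' @export
write_similarity <- function(m, path) {
  df <- as.data.frame(unclass(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @param subject_id,atlas_name metadata to attach on read.
#' @export
read_similarity <- function(path, subject_id = basename(path),
                            atlas_name = "custom") {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  structure(m, class = c("similarity_matrix", "matrix", "array"),
            subject_id = subject_id, atlas_name = atlas_name)
}
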