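#' Metric curves over the sparsity range, with AUC summaries
#'
#' Thresholds one similarity matrix at each sparsity in `grid`, computes the
#' requested global metrics (`e_glob`, `e_loc`, `cp`, `lp`, and the
#' small-world indices `gamma`/`lambda`/`sigma`) and nodal metrics
#' (`degree`, `nodal_efficiency`, `betweenness`), and summarizes every curve
#' by its trapezoidal area under the curve over the sparsity range.
#'
#' Small-world indices are by far the most expensive (each threshold needs a
#' rewired null ensemble), so callers that do not need them — e.g. large
#' simulation studies — should drop them from `global_metrics`.
#'
#' @param m similarity matrix (see [build_network()]).
#' @param grid a [sparsity_grid()].
#' @param mode `"weighted"` (default) or `"binary"`.
#' @param global_metrics subset of
#'   `c("e_glob", "e_loc", "cp", "lp", "gamma", "lambda", "sigma")`.
#' @param nodal_metrics subset of
#'   `c("degree", "nodal_efficiency", "betweenness")`.
#' @param null_config list with `n_null` and `n_swaps_per_edge` for the
#'   small-world null ensembles.
#' @param seed RNG seed used for the null ensembles.
#' @return a `metric_curves` object: `thresholds`, `global` (data frame of
#'   per-threshold values), `nodal` (list of node x threshold matrices),
#'   `auc_global` (named numeric), `auc_nodal` (list of named vectors),
#'   `disconnected` (per-threshold flag), `mode`.
#' @export
metric_curves <- function(m, grid = sparsity_grid(),
                          mode = c("weighted", "binary"),
                          global_metrics = c("e_glob", "e_loc", "cp", "lp",
                                             "gamma", "lambda", "sigma"),
                          nodal_metrics = c("degree", "nodal_efficiency",
                                            "betweenness"),
                          null_config = list(n_null = 100L,
                                             n_swaps_per_edge = 10L),
                          seed = NULL) {
  mode <- match.arg(mode)
  global_metrics <- match.arg(global_metrics, several.ok = TRUE)
  if (length(nodal_metrics)) {
    nodal_metrics <- match.arg(nodal_metrics, several.ok = TRUE)
  }
  ths <- grid$thresholds
  nt <- length(ths)
  n <- nrow(m)
  want_sw <- any(c("gamma", "lambda", "sigma") %in% global_metrics)
  if (!is.null(seed)) set.seed(seed)
  glob <- matrix(NA_real_, nt, length(global_metrics),
                 dimnames = list(NULL, global_metrics))
  nodal <- lapply(nodal_metrics, function(x) {
    matrix(NA_real_, n, nt, dimnames = list(rownames(m), NULL))
  })
  names(nodal) <- nodal_metrics
  disconnected <- logical(nt)
  rk <- edge_ranking(unclass(m))  # one sort shared by all thresholds

  for (t in seq_len(nt)) {
    s <- ths[t]
    step <- function(expr) {
      tryCatch(expr, morphnet_error = function(e) {
        stop_morphnet("at sparsity %.2f: %s", s, conditionMessage(e),
                      class = class(e)[1])
      })
    }
    g <- step(tg_from_ranking(rk, s, mode, dimnames(m)))
    pe <- NULL
    if (any(c("e_glob", "lp") %in% global_metrics) ||
        "nodal_efficiency" %in% nodal_metrics || want_sw) {
      pe <- path_and_efficiency(g)
      disconnected[t] <- pe$disconnected
    }
    if ("e_glob" %in% global_metrics) glob[t, "e_glob"] <- pe$e_glob
    if ("lp" %in% global_metrics) glob[t, "lp"] <- pe$lp
    if ("cp" %in% global_metrics) {
      glob[t, "cp"] <- clustering_coefficient(g)$cp
    }
    if ("e_loc" %in% global_metrics) {
      glob[t, "e_loc"] <- local_efficiency(g)$e_loc
    }
    if (want_sw) {
      sw <- step(small_world_indices(g, n_null = null_config$n_null %||% 100L,
                                     n_swaps_per_edge =
                                       null_config$n_swaps_per_edge %||% 10L))
      for (nm in intersect(c("gamma", "lambda", "sigma"), global_metrics)) {
        glob[t, nm] <- sw[[nm]]
      }
    }
    if ("degree" %in% nodal_metrics) nodal$degree[, t] <- nodal_degree(g)
    if ("nodal_efficiency" %in% nodal_metrics) {
      nodal$nodal_efficiency[, t] <- pe$nodal_efficiency
    }
    if ("betweenness" %in% nodal_metrics) {
      nodal$betweenness[, t] <- node_betweenness(g)
    }
  }

  auc_global <- apply(glob, 2, function(y) trapz_auc(ths, y))
  auc_nodal <- lapply(nodal, function(mat) {
    setNames(apply(mat, 1, function(y) trapz_auc(ths, y)), rownames(mat))
  })
  structure(list(thresholds = ths,
                 global = data.frame(sparsity = ths, glob,
                                     check.names = FALSE),
                 nodal = nodal, auc_global = auc_global,
                 auc_nodal = auc_nodal, disconnected = disconnected,
                 mode = mode, subject_id = attr(m, "subject_id")),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("<metric_curves> subject %s, %d thresholds [%.2f, %.2f], mode %s\n",
              x$subject_id %||% "?", length(x$thresholds),
              min(x$thresholds), max(x$thresholds), x$mode))
  cat("global AUC:\n")
  print(round(x$auc_global, 4))
  invisible(x)
}

#' Tidy long-format export of metric curves
#'
#' @param x a `metric_curves` object.
#' @param path optional TSV path; when given the table is also written there.
#' @return data frame with columns subject, metric, node, sparsity, value.
#' @export
curves_to_long <- function(x, path = NULL) {
  subj <- x$subject_id %||% "subject"
  glob <- x$global
  gm <- setdiff(names(glob), "sparsity")
  out <- do.call(rbind, c(
    lapply(gm, function(m) {
      data.frame(subject = subj, metric = m, node = "global",
                 sparsity = glob$sparsity, value = glob[[m]])
    }),
    lapply(names(x$nodal), function(m) {
      mat <- x$nodal[[m]]
      data.frame(subject = subj, metric = m,
                 node = rep(rownames(mat) %||%
                              paste0("n", seq_len(nrow(mat))), ncol(mat)),
                 sparsity = rep(x$thresholds, each = nrow(mat)),
                 value = as.vector(mat))
    })))
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
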