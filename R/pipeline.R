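#' Configuration of a full pipeline run
#'
#' Collects every knob of the simulate -> extract -> network -> metrics ->
#' stats -> report chain. Either a [cohort_config()] (synthetic mode) or a
#' `manifest` CSV (subject_id, group, covariates, plus per-subject sample
#' TSV paths in a `samples_path` column) must be supplied.
#'
#' @param out_dir output directory; created if missing.
#' @param cohort cohort configuration for synthetic mode.
#' @param manifest path to a cohort manifest CSV (real-data mode).
#' @param grid_size,bandwidth_rule,gm_floor network-construction options.
#' @param sparsity a [sparsity_grid()].
#' @param mode `"weighted"` or `"binary"` graph mode.
#' @param small_world whether to compute gamma/lambda/sigma curves (null
#'   ensembles make this by far the most expensive stage).
#' @param null_config list with `n_null`, `n_swaps_per_edge`.
#' @param covariates nuisance covariates for the ANCOVA / correlations.
#' @param alpha significance gate for post hoc tests.
#' @param correlation_subset groups pooled for clinical correlations
#'   (default the two patient groups).
#' @param clinical_vars clinical variables correlated with nodal degree.
#' @param seed seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       manifest = NULL,
                       grid_size = 128L, bandwidth_rule = "silverman",
                       gm_floor = 0,
                       sparsity = sparsity_grid(),
                       mode = "weighted",
                       small_world = FALSE,
                       null_config = list(n_null = 100L,
                                          n_swaps_per_edge = 10L),
                       covariates = c("age", "gender", "education", "TIV"),
                       alpha = 0.05,
                       correlation_subset = c("DM", "DKD"),
                       clinical_vars = c("eGFR", "Scr", "NCTA"),
                       seed = 42L) {
  structure(list(out_dir = out_dir, cohort = cohort, manifest = manifest,
                 grid_size = as.integer(grid_size),
                 bandwidth_rule = bandwidth_rule, gm_floor = gm_floor,
                 sparsity = sparsity, mode = mode,
                 small_world = isTRUE(small_world),
                 null_config = null_config, covariates = covariates,
                 alpha = alpha, correlation_subset = correlation_subset,
                 clinical_vars = clinical_vars, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / load a run configuration
#'
#' JSON is the primary format; a `.yaml`/`.yml` path is read with the yaml
#' package when it is installed.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$cohort)) {
    co <- unclass(cfg$cohort)
    # jsonlite drops names on atomic vectors; keep them via lists
    for (f in c("group_sizes", "effect_grades", "male_prop")) {
      co[[f]] <- as.list(co[[f]])
    }
    cfg$cohort <- co
  }
  cfg$sparsity <- unclass(cfg$sparsity)[c("s_min", "s_max", "step")]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_morphnet("yaml package not installed; use a JSON config",
                    class = "morphnet_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort <- if (!is.null(cfg$cohort)) {
    cc <- cfg$cohort
    cohort_config(
      group_sizes = unlist(cc$group_sizes),
      n_rois = cc$n_rois,
      voxels_per_roi = unlist(cc$voxels_per_roi),
      affected_rois = unlist(cc$affected_rois),
      effect_grades = unlist(cc$effect_grades),
      clinical_params = lapply(cc$clinical_params,
                               function(v) lapply(v, unlist)),
      male_prop = unlist(cc$male_prop),
      min_voxels = cc$min_voxels,
      seed = cc$seed)
  }
  run_config(out_dir = cfg$out_dir, cohort = cohort,
             manifest = cfg$manifest,
             grid_size = cfg$grid_size, bandwidth_rule = cfg$bandwidth_rule,
             gm_floor = cfg$gm_floor,
             sparsity = do.call(sparsity_grid, as.list(cfg$sparsity)),
             mode = cfg$mode, small_world = cfg$small_world,
             null_config = cfg$null_config, covariates = cfg$covariates,
             alpha = cfg$alpha,
             correlation_subset = cfg$correlation_subset,
             clinical_vars = cfg$clinical_vars, seed = cfg$seed)
}

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

hash_files <- function(paths) {
  unname(tools::md5sum(sort(paths)))
}

stage_log <- function(stage, msg, t0 = NULL) {
  elapsed <- if (!is.null(t0)) {
    sprintf(" [%.1fs]", as.numeric(Sys.time()) - as.numeric(t0))
  } else ""
  message(sprintf("[morphnet] %-8s %s%s", stage, msg, elapsed))
}

read_stage_state <- function(out_dir) {
  p <- file.path(out_dir, "run_manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_stage_state <- function(out_dir, state) {
  jsonlite::write_json(state, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_fresh <- function(state, stage, input_hash, outputs) {
  !is.null(state[[stage]]) &&
    identical(unname(unlist(state[[stage]]$input_hash)), unname(input_hash)) &&
    all(file.exists(outputs))
}

#' Run the full pipeline
#'
#' Executes simulate -> network -> metrics -> stats -> report, persisting
#' each stage's outputs under `config$out_dir` and skipping a stage when its
#' recorded input hash matches and its outputs exist. A run manifest
#' (`run_manifest.json`) records the config hash, seeds, package version and
#' per-stage input/output hashes.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run (dependencies must already have
#'   outputs on disk).
#' @return invisibly, a list with the stats bundle and key file paths.
#' @export
run_all <- function(config, stages = c("simulate", "network", "metrics",
                                       "stats", "report")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in c("", "samples", "networks", "metrics", "results", "report")) {
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  }
  state <- read_stage_state(out)
  state$package_version <- as.character(utils::packageVersion("morphnet"))
  state$seed <- config$seed
  cohort_csv <- file.path(out, "cohort.csv")

  ## ---- simulate ----
  if ("simulate" %in% stages && !is.null(config$cohort)) {
    h <- hash_object(unclass(config$cohort))
    ids <- NULL
    if (!stage_fresh(state, "simulate", h, cohort_csv)) {
      t0 <- Sys.time()
      sim <- generate_cohort(config$cohort)
      write_cohort(sim$cohort, cohort_csv)
      for (s in sim$samples) {
        write_roi_samples(s, file.path(out, "samples",
                                       paste0(s$subject_id, ".tsv")))
      }
      state$simulate <- list(input_hash = h,
                             n_subjects = nrow(sim$cohort))
      stage_log("simulate", sprintf("%d subjects, %d ROIs",
                                    nrow(sim$cohort), config$cohort$n_rois),
                t0)
      write_stage_state(out, state)
    } else {
      stage_log("simulate", "up to date, skipped")
    }
  } else if (!is.null(config$manifest)) {
    file.copy(config$manifest, cohort_csv, overwrite = TRUE)
  }

  cohort <- read_cohort(cohort_csv)
  ids <- cohort$subject_id
  sample_paths <- if (!is.null(cohort$samples_path)) cohort$samples_path else
    file.path(out, "samples", paste0(ids, ".tsv"))
  net_paths <- file.path(out, "networks", paste0(ids, ".tsv"))

  ## ---- network ----
  if ("network" %in% stages) {
    h <- c(hash_files(sample_paths),
           hash_object(config[c("grid_size", "bandwidth_rule")]))
    if (!stage_fresh(state, "network", h, net_paths)) {
      t0 <- Sys.time()
      for (i in seq_along(ids)) {
        s <- read_roi_samples(sample_paths[i], subject_id = ids[i])
        m <- build_network(s, grid_size = config$grid_size,
                           bandwidth_rule = config$bandwidth_rule)
        write_similarity(m, net_paths[i])
      }
      state$network <- list(input_hash = h)
      stage_log("network", sprintf("%d similarity matrices", length(ids)), t0)
      write_stage_state(out, state)
    } else {
      stage_log("network", "up to date, skipped")
    }
  }

  ## ---- metrics ----
  gmetrics <- c("e_glob", "e_loc", "cp", "lp",
                if (config$small_world) c("gamma", "lambda", "sigma"))
  nmetrics <- c("degree", "nodal_efficiency", "betweenness")
  auc_global_path <- file.path(out, "metrics", "auc_global.tsv")
  auc_nodal_paths <- file.path(out, "metrics",
                               paste0("auc_nodal_", nmetrics, ".tsv"))
  if ("metrics" %in% stages) {
    h <- c(hash_files(net_paths),
           hash_object(config[c("sparsity", "mode", "small_world",
                                "null_config", "seed")]))
    if (!stage_fresh(state, "metrics", h,
                     c(auc_global_path, auc_nodal_paths))) {
      t0 <- Sys.time()
      auc_g <- NULL
      auc_n <- setNames(vector("list", length(nmetrics)), nmetrics)
      for (i in seq_along(ids)) {
        m <- read_similarity(net_paths[i], subject_id = ids[i])
        mc <- metric_curves(m, grid = config$sparsity, mode = config$mode,
                            global_metrics = gmetrics,
                            nodal_metrics = nmetrics,
                            null_config = config$null_config,
                            seed = config$seed + i)
        curves_to_long(mc, file.path(out, "metrics",
                                     paste0(ids[i], "_curves.tsv")))
        auc_g <- rbind(auc_g, mc$auc_global)
        for (nm in nmetrics) auc_n[[nm]] <- rbind(auc_n[[nm]],
                                                  mc$auc_nodal[[nm]])
      }
      write.table(data.frame(subject_id = ids, auc_g, check.names = FALSE),
                  auc_global_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      for (k in seq_along(nmetrics)) {
        write.table(data.frame(subject_id = ids, auc_n[[nmetrics[k]]],
                               check.names = FALSE),
                    auc_nodal_paths[k], sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      state$metrics <- list(input_hash = h)
      stage_log("metrics", sprintf("%d subjects x %d thresholds",
                                   length(ids),
                                   length(config$sparsity$thresholds)), t0)
      write_stage_state(out, state)
    } else {
      stage_log("metrics", "up to date, skipped")
    }
  }

  ## ---- stats ----
  bundle_path <- file.path(out, "results", "bundle.json")
  global_tsv <- file.path(out, "results", "global_ancova.tsv")
  nodal_tsv <- file.path(out, "results", "nodal_screen.tsv")
  corr_tsv <- file.path(out, "results", "correlations.tsv")
  if ("stats" %in% stages) {
    h <- c(hash_files(c(auc_global_path, auc_nodal_paths, cohort_csv)),
           hash_object(config[c("covariates", "alpha",
                                "correlation_subset", "clinical_vars")]))
    if (!stage_fresh(state, "stats", h, c(bundle_path, global_tsv,
                                          nodal_tsv, corr_tsv))) {
      t0 <- Sys.time()
      res <- pipeline_stats(config, cohort, auc_global_path, auc_nodal_paths,
                            nmetrics)
      write.table(res$global, global_tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(res$nodal, nodal_tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(res$correlations, corr_tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(
        list(settings = list(covariates = config$covariates,
                             alpha = config$alpha, mode = config$mode,
                             seed = config$seed,
                             correlation_subset = config$correlation_subset),
             global = res$global, nodal = res$nodal,
             correlations = res$correlations),
        bundle_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      state$stats <- list(input_hash = h,
                          output_hash = hash_files(c(global_tsv, nodal_tsv,
                                                     corr_tsv)))
      stage_log("stats", "group inference complete", t0)
      write_stage_state(out, state)
    } else {
      stage_log("stats", "up to date, skipped")
    }
  }

  ## ---- report ----
  if ("report" %in% stages) {
    t0 <- Sys.time()
    report_run(out)
    stage_log("report", "tables and figures written", t0)
  }
  invisible(list(out_dir = out,
                 cohort = cohort,
                 global = if (file.exists(global_tsv))
                   read.delim(global_tsv),
                 nodal = if (file.exists(nodal_tsv)) read.delim(nodal_tsv),
                 correlations = if (file.exists(corr_tsv))
                   read.delim(corr_tsv)))
}

pipeline_stats <- function(config, cohort, auc_global_path, auc_nodal_paths,
                           nmetrics) {
  auc_g <- read.delim(auc_global_path, check.names = FALSE)
  stopifnot(identical(auc_g$subject_id, cohort$subject_id))
  gm <- setdiff(names(auc_g), "subject_id")
  global <- do.call(rbind, lapply(gm, function(metric) {
    res <- ancova_group_test(auc_g[[metric]], cohort, config$covariates)
    ph <- bonferroni_posthoc(res)
    row <- data.frame(metric = metric, F = res$statistic, df1 = res$df[1],
                      df2 = res$df[2], p = res$p)
    for (nm in names(ph)) {
      key <- gsub("-", "_vs_", nm)
      row[[paste0("p_bonf_", key)]] <-
        if (isTRUE(res$p < config$alpha)) ph[[nm]]$p_adjusted else NA_real_
      row[[paste0("dir_", key)]] <- ph[[nm]]$direction
    }
    row
  }))
  nodal <- do.call(rbind, lapply(seq_along(nmetrics), function(k) {
    tab <- read.delim(auc_nodal_paths[k], check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    nodal_group_screen(mat, cohort, config$covariates, config$alpha,
                       metric = nmetrics[k])
  }))
  # clinical correlations: nodal degree of nodes significant in the screen,
  # within the configured patient subset, adjusted for nuisance covariates
  deg_tab <- read.delim(auc_nodal_paths[match("degree", nmetrics)],
                        check.names = FALSE)
  deg_nodes <- nodal$node[nodal$metric == "degree" &
                            !is.na(nodal$p) & nodal$p < config$alpha]
  sub <- cohort$group %in% config$correlation_subset
  correlations <- data.frame()
  for (nd in deg_nodes) {
    for (cv in config$clinical_vars) {
      if (!cv %in% names(cohort)) next
      res <- tryCatch(
        adjusted_correlation(deg_tab[[nd]][sub], cohort[[cv]][sub],
                             cohort[sub, , drop = FALSE],
                             config$covariates),
        error = function(e) NULL)
      if (is.null(res)) next
      correlations <- rbind(correlations, data.frame(
        node = nd, variable = cv, r = res$estimate, df = res$df, p = res$p))
    }
  }
  if (!nrow(correlations)) {
    correlations <- data.frame(node = character(), variable = character(),
                               r = numeric(), df = numeric(), p = numeric())
  }
  list(global = global, nodal = nodal, correlations = correlations)
}

#' Extract per-ROI samples for every subject of a volume manifest
#'
#' The NIfTI entry point of the pipeline: reads a manifest CSV with columns
#' `subject_id`, `gm_path` and `atlas_path` (per-subject gray-matter map and
#' co-registered label atlas) and writes one ROI-sample TSV per subject under
#' `out_dir/samples/`, ready for the network stage.
#'
#' @param manifest path to the manifest CSV.
#' @param out_dir run output directory.
#' @param spec an [atlas_spec()]; when `NULL` it is inferred from the labels
#'   of the first atlas volume.
#' @param gm_floor,min_voxels see [extract_roi_samples()].
#' @return invisibly, the paths of the written sample TSVs.
#' @export
pipeline_extract <- function(manifest, out_dir, spec = NULL, gm_floor = 0,
                             min_voxels = 10L) {
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  for (col in c("subject_id", "gm_path", "atlas_path")) {
    if (is.null(mf[[col]])) {
      stop_morphnet("manifest lacks required column '%s'", col,
                    class = "morphnet_config_error")
    }
  }
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE,
             recursive = TRUE)
  paths <- character(nrow(mf))
  for (i in seq_len(nrow(mf))) {
    atlas <- read_nifti(mf$atlas_path[i])
    if (is.null(spec)) {
      labs <- sort(unique(as.vector(atlas$data)))
      labs <- labs[labs > 0]
      spec <- atlas_spec("manifest", length(labs), as.integer(labs))
    }
    rs <- extract_roi_samples(read_nifti(mf$gm_path[i]), atlas, spec,
                              gm_floor = gm_floor, min_voxels = min_voxels,
                              subject_id = mf$subject_id[i])
    paths[i] <- file.path(out_dir, "samples",
                          paste0(mf$subject_id[i], ".tsv"))
    write_roi_samples(rs, paths[i])
  }
  stage_log("extract", sprintf("%d subjects, %d ROIs", nrow(mf),
                               spec$n_rois))
  invisible(paths)
}

#' Regenerate report tables and figures from a completed run
#'
#' Emits the group-comparison table for the seven global metrics, the
#' per-node significant-findings table, violin-style plots of the global AUC
#' distributions by group, and scatter plots of the adjusted clinical
#' correlations.
#'
#' @param out_dir output directory of a completed [run_all()].
#' @return invisibly, paths of the written report files.
#' @export
report_run <- function(out_dir) {
  need <- c(cohort = file.path(out_dir, "cohort.csv"),
            auc = file.path(out_dir, "metrics", "auc_global.tsv"),
            global = file.path(out_dir, "results", "global_ancova.tsv"),
            nodal = file.path(out_dir, "results", "nodal_screen.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop_morphnet("missing stage outputs for report: %s",
                  paste(names(missing), collapse = ", "),
                  class = "morphnet_pipeline_error")
  }
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  cohort <- read_cohort(need[["cohort"]])
  auc_g <- read.delim(need[["auc"]], check.names = FALSE)
  global <- read.delim(need[["global"]])
  nodal <- read.delim(need[["nodal"]])

  gtab_path <- file.path(rep_dir, "global_comparison.tsv")
  write.table(global, gtab_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sig <- nodal[!is.na(nodal$p) & nodal$p < 0.05, , drop = FALSE]
  ntab_path <- file.path(rep_dir, "nodal_significant.tsv")
  write.table(sig, ntab_path, sep = "\t", quote = FALSE, row.names = FALSE)

  long <- do.call(rbind, lapply(setdiff(names(auc_g), "subject_id"),
                                function(m) {
    data.frame(group = cohort$group, metric = m, auc = auc_g[[m]])
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = group, y = auc,
                                          fill = group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "AUC over sparsity range")
  violin_path <- file.path(rep_dir, "global_violin.png")
  ggplot2::ggsave(violin_path, p, width = 9, height = 6, dpi = 120)

  corr_path <- file.path(out_dir, "results", "correlations.tsv")
  scatter_path <- NULL
  if (file.exists(corr_path)) {
    corr <- read.delim(corr_path)
    if (nrow(corr)) {
      deg <- read.delim(file.path(out_dir, "metrics",
                                  "auc_nodal_degree.tsv"),
                        check.names = FALSE)
      pick <- corr[order(corr$p), ][seq_len(min(6, nrow(corr))), ]
      sc <- do.call(rbind, lapply(seq_len(nrow(pick)), function(i) {
        data.frame(panel = sprintf("%s vs %s (r=%.2f)", pick$node[i],
                                   pick$variable[i], pick$r[i]),
                   x = cohort[[pick$variable[i]]],
                   y = deg[[pick$node[i]]], group = cohort$group)
      }))
      ps <- ggplot2::ggplot(sc, ggplot2::aes(x = x, y = y,
                                             color = group)) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             color = "black", linewidth = 0.4) +
        ggplot2::facet_wrap(~panel, scales = "free") +
        ggplot2::theme_minimal() +
        ggplot2::labs(x = "clinical variable", y = "degree AUC")
      scatter_path <- file.path(rep_dir, "correlation_scatter.png")
      ggplot2::ggsave(scatter_path, ps, width = 9, height = 6, dpi = 120)
    }
  }
  invisible(c(gtab_path, ntab_path, violin_path, scatter_path))
}

#' Command-line interface
#'
#' Thin wrapper so the pipeline can be driven from a shell:
#' `Rscript -e 'morphnet::morphnet_cli()' run-all --config cfg.json`.
#' Subcommands: `simulate`, `extract`, `network`, `metrics`, `stats`,
#' `report`, `run-all`. Flags: `--config <path>` (JSON, or YAML when the
#' yaml package is installed), `--out <dir>`, `--seed <int>` and
#' `--manifest <csv>` (for `extract`) override the config.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly.
#' @export
morphnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: morphnet <simulate|network|metrics|stats|report|run-all> ",
            "[--config cfg.json] [--out dir] [--seed n]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opt$config)) read_run_config(opt$config) else
    run_config(out_dir = opt$out %||% "morphnet_run")
  if (!is.null(opt$out)) config$out_dir <- opt$out
  if (!is.null(opt$seed)) {
    config$seed <- as.integer(opt$seed)
    if (!is.null(config$cohort)) config$cohort$seed <- as.integer(opt$seed)
  }
  if (cmd == "extract") {
    pipeline_extract(opt$manifest %||% config$manifest, config$out_dir,
                     gm_floor = config$gm_floor)
    return(invisible(0L))
  }
  stages <- switch(cmd,
    "run-all" = c("simulate", "network", "metrics", "stats", "report"),
    "simulate" = "simulate",
    "network" = "network",
    "metrics" = "metrics",
    "stats" = "stats",
    "report" = "report",
    stop_morphnet("unknown subcommand '%s'", cmd,
                  class = "morphnet_config_error"))
  run_all(config, stages = stages)
  invisible(0L)
}
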