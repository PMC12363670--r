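PIPELINE_KEYS <- list(
  top = c("seed", "output_dir", "simulate", "reference", "query",
          "select_features", "tune", "model", "predict", "explain"),
  simulate = c("preset", "n_states", "cells_per_state", "n_genes",
               "markers_per_state", "marker_fold_change", "dispersion",
               "library_size_sigma", "query_cells_per_state",
               "batch_shift_sigma", "novel_states"),
  reference = c("matrix", "format", "labels"),
  query = c("matrix", "format"),
  select_features = c("enabled", "rounds", "retain_fraction",
                      "background_size"),
  tune = c("enabled", "C", "class_weight", "max_iter"),
  model = c("C", "class_weight", "max_iter", "folds", "target_sum",
            "n_top_hvg"),
  predict = c("tau_low", "tau_high", "max_missing"),
  explain = c("n_top"))

validate_config <- function(config) {
  check <- function(keys, valid, where) {
    bad <- setdiff(keys, valid)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "), "; valid keys: ",
           paste(valid, collapse = ", "))
  }
  check(names(config), PIPELINE_KEYS$top, "top level")
  for (sec in intersect(names(config), names(PIPELINE_KEYS)[-1]))
    check(names(config[[sec]]), PIPELINE_KEYS[[sec]], sec)
  if (is.null(config$simulate) && is.null(config$reference))
    stop("config must provide either a 'simulate' or a 'reference' section")
  invisible(config)
}

log_stage <- function(level, stage, message)
  cat(sprintf("%s\t%s\t%s\n", level, stage, message), file = stderr())

#' Run the end-to-end annotation workflow
#'
#' Executes, in order: simulate or load the reference; preprocess;
#' Shapley-driven feature elimination; optional hyperparameter tuning;
#' train; calibrate; predict the query; explain; summarize.  All outputs
#' (gene panel, elimination report, model bundle, prediction table,
#' explanation table, summary, run manifest) are written to `output_dir`.
#' Reruns with an identical config produce byte-identical prediction
#' tables.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure (requires the `yaml` package).  Sections: `simulate` (or
#'   `reference`/`query` file inputs), `select_features`, `tune`, `model`,
#'   `predict`, `explain`; top-level `seed` and `output_dir`.
#' @param output_dir overrides `config$output_dir`.
#' @param seed overrides `config$seed` (default 0).
#' @return invisibly, a list with the fitted model, predictions, summary,
#'   and manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  t_start <- Sys.time()
  config_path <- NULL
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- as.integer(seed %||% config$seed %||% 0L)
  output_dir <- output_dir %||% config$output_dir %||% stop("no output_dir")
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  warnings_seen <- character(0)
  input_hashes <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    log_stage("INFO", name, "start")
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen,
                          paste0(name, ": ", conditionMessage(w)))
      log_stage("WARN", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[name]] <<- dt
    log_stage("INFO", name, sprintf("done in %.2fs", dt))
    res
  }

  mcfg <- config$model %||% list()
  cfg <- model_config(C = mcfg$C %||% 0.01,
                      class_weight = mcfg$class_weight %||% "balanced",
                      max_iter = mcfg$max_iter %||% 1000L,
                      folds = mcfg$folds %||% 5L,
                      seed = seed)
  target_sum <- mcfg$target_sum %||% 1e4
  n_top_hvg <- mcfg$n_top_hvg %||% 2000L

  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim_cfg <- if (!is.null(sc$preset)) simulation_preset(sc$preset, seed)
      else simulation_config(
        n_states = sc$n_states %||% 15L,
        cells_per_state = sc$cells_per_state %||% 200L,
        n_genes = sc$n_genes %||% 2000L,
        markers_per_state = sc$markers_per_state %||% 30L,
        marker_fold_change = sc$marker_fold_change %||% 8,
        dispersion = sc$dispersion %||% 2,
        library_size_sigma = sc$library_size_sigma %||% 0.3,
        seed = seed)
    sim <- stage("simulate", simulate_atlas(sim_cfg))
    ref <- sim$atlas
  } else {
    rc <- config$reference
    if (is.null(rc$matrix) || is.null(rc$labels))
      stop("reference section needs 'matrix' and 'labels' paths")
    ref <- stage("load", {
      m <- read_matrix(rc$matrix, rc$format %||% "mtx")
      ReferenceAtlas(m, read_labels(rc$labels, m$cell_ids))
    })
    input_hashes[rc$matrix] <- unname(tools::md5sum(rc$matrix))
    input_hashes[rc$labels] <- unname(tools::md5sum(rc$labels))
  }

  fs <- config$select_features %||% list()
  if (isFALSE(fs$enabled)) {
    panel <- ref$matrix$gene_ids
    elim <- NULL
  } else {
    elim <- stage("select_features",
      recursive_elimination(ref,
                            rounds = fs$rounds %||% 4L,
                            retain_fraction = fs$retain_fraction %||% 0.5,
                            background_size = fs$background_size %||% 1000L,
                            model_cfg = cfg, target_sum = target_sum,
                            n_top_hvg = n_top_hvg, seed = seed))
    panel <- elim$gene_panel
    writeLines(panel, file.path(output_dir, "panel.txt"))
    write.table(elim$report,
                file.path(output_dir, "elimination_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(config$tune$enabled)) {
    grid <- config$tune
    cfg$tuning_grid <- list(C = grid$C %||% cfg$tuning_grid$C,
                            class_weight = grid$class_weight %||% "balanced",
                            max_iter = grid$max_iter %||% cfg$max_iter)
    tuned <- stage("tune", tune_model(ref, panel, cfg, target_sum))
    cfg <- tuned$best
    write.table(tuned$grid, file.path(output_dir, "tuning_grid.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  model <- stage("train", fit_model(ref, panel, cfg, target_sum, n_top_hvg))
  model <- stage("calibrate", calibrate_model(model, ref))
  save_model(model, file.path(output_dir, "model.rds"))

  if (!is.null(config$query$matrix)) {
    qc <- config$query
    query <- stage("load_query", read_matrix(qc$matrix, qc$format %||% "mtx"))
    input_hashes[qc$matrix] <- unname(tools::md5sum(qc$matrix))
  } else if (!is.null(sim)) {
    sc <- config$simulate
    query <- stage("simulate_query",
      simulate_query(sim,
                     cells_per_state = sc$query_cells_per_state %||% 100L,
                     batch_shift_sigma = sc$batch_shift_sigma %||% 0,
                     novel_states = sc$novel_states %||% 0L,
                     seed = seed + 1L)$matrix)
  } else {
    query <- NULL
  }

  result <- list(model = model, elimination = elim)
  if (!is.null(query)) {
    pc <- config$predict %||% list()
    thresholds <- certainty_thresholds(pc$tau_low %||% 0.3,
                                       pc$tau_high %||% 0.7)
    records <- stage("predict",
      predict(model, query, thresholds,
              max_missing = pc$max_missing %||% 0.5))
    data.table::fwrite(records, file.path(output_dir, "pred.tsv"),
                       sep = "\t")
    explain <- stage("explain",
      top_explainable_genes(model, query, records,
                            n_top = config$explain$n_top %||% 10L))
    etab <- do.call(rbind, lapply(names(explain), function(st)
      if (nrow(explain[[st]]))
        data.frame(state = st, rank = seq_len(nrow(explain[[st]])),
                   explain[[st]])))
    write.table(etab, file.path(output_dir, "explain.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- stage("summarize", summarize_predictions(records))
    jsonlite::write_json(list(bin_counts = as.list(summary$bin_counts),
                              bin_percent = as.list(summary$bin_percent),
                              per_state = summary$per_state),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    result$predictions <- records
    result$summary <- summary
  }

  manifest <- list(
    tool = "cellstateR",
    version = as.character(packageVersion("cellstateR")),
    seed = seed,
    config = config,
    config_path = config_path,
    input_hashes = input_hashes,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_seconds = timings,
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  result$manifest <- manifest
  invisible(result)
}
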