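#' Pipeline run configuration
#'
#' Bundles every stage's parameters with a single master seed. Stage
#' defaults are the pipeline's canonical settings: QC at total counts >
#' 800 / genes > 500 / mito < 10 %, normalization to 10,000 counts per
#' cell, 2,000 HVGs, 30 principal components, minimal cosine distance, a
#' 23-point percentage grid, 20 stratified 80/20 splits and an MI bin
#' floor of 50 cells.
#'
#' @param input path to a labeled expression CSV, or `NULL` when a
#'   `synthetic` config is given.
#' @param synthetic optional [synthetic_config()]; when set, data are
#'   generated instead of read.
#' @param qc a [qc_thresholds()].
#' @param technical_prefixes prefixes of technical features to drop.
#' @param preprocess a [preprocess_config()].
#' @param distance a [distance_config()].
#' @param p_grid percentage grid for the sweep.
#' @param n_splits,train_fraction classifier evaluation protocol.
#' @param binning a [binning_config()].
#' @param mi_top_k genes kept as "MI genes" for the strategy comparison.
#' @param seed master seed fanned out to all randomized stages.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       qc = qc_thresholds(),
                       technical_prefixes = "CMO",
                       preprocess = preprocess_config(),
                       distance = distance_config(),
                       p_grid = default_p_grid(),
                       n_splits = 20L, train_fraction = 0.8,
                       binning = binning_config(),
                       mi_top_k = 10L, seed = 1L) {
  if (is.null(input) && is.null(synthetic))
    stop("provide either `input` or a `synthetic` config")
  structure(list(input = input, synthetic = synthetic, qc = qc,
                 technical_prefixes = technical_prefixes,
                 preprocess = preprocess, distance = distance,
                 p_grid = p_grid, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, binning = binning,
                 mi_top_k = as.integer(mi_top_k),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full stratification pipeline
#'
#' Executes QC filtering, technical-feature removal, preprocessing (PCA
#' embedding), the predicted-sensitive percentage sweep, stratification at
#' the sweep's best cutoff, MI gene ranking of predicted-sensitive versus
#' treated cells, and the three-strategy classifier comparison; every
#' intermediate is written to `out_dir` as CSV together with a
#' machine-readable JSON manifest (config echo, seed, package version,
#' per-stage dimensions, wall-clock). A failing stage aborts with the
#' stage name, which is also recorded in the manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `qc_report`,
#'   `embedding`, `sweep`, `stratification`, `mi_ranking`, `reports`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("scStratify")),
                   seed = config$seed, stages = list())
  current_stage <- NA_character_
  stage <- function(name) current_stage <<- name
  log_dim <- function(name, m)
    manifest$stages[[name]] <<- list(genes = nrow(m$counts),
                                     cells = ncol(m$counts))
  res <- tryCatch({
    stage("input")
    if (!is.null(config$synthetic)) {
      sim <- simulate_expression(config$synthetic)
      m <- sim$matrix
      write_labeled_csv(m, file.path(out_dir, "input_matrix.csv"))
      write_ground_truth_csv(sim$truth, file.path(out_dir, "ground_truth"))
    } else {
      m <- read_labeled_csv(config$input)
    }
    log_dim("input", m)

    stage("qc")
    qc <- qc_filter_cells(m, config$qc)
    write_qc_report(qc$report, file.path(out_dir, "qc_report.csv"))
    m <- drop_technical_features(qc$matrix, config$technical_prefixes)
    log_dim("qc", m)

    stage("preprocess")
    prep <- preprocess(m, config$preprocess)
    write_embedding_csv(prep$embedding, file.path(out_dir, "embedding.csv"))

    stage("sweep")
    sweep_res <- sensitivity_sweep(prep$lognorm, prep$embedding,
                                   config$distance, config$p_grid,
                                   n_splits = config$n_splits,
                                   train_fraction = config$train_fraction,
                                   seed = config$seed)
    write_sweep_csv(sweep_res, file.path(out_dir, "sweep_curve.csv"))

    stage("stratify")
    p_best <- sweep_res$argmax_p
    strat <- stratify_cells(sweep_res$scores, p_best)
    write_stratification_csv(strat, file.path(out_dir, "stratification.csv"))

    stage("mi_rank")
    sens <- predicted_sensitive(strat)
    trt <- names(prep$lognorm$labels)[prep$lognorm$labels == 1L]
    sub <- subset_cells(prep$lognorm, c(sens, trt))
    ranking <- rank_genes_mi(sub, config$binning)
    write_mi_ranking_csv(ranking, file.path(out_dir, "mi_ranking.csv"))

    stage("classify")
    strategies <- list(
      top_mi = gene_selection("top_mi", k = config$mi_top_k),
      random = gene_selection("random", k = config$mi_top_k,
                              seed = config$seed),
      all_nonconstant = gene_selection("all_nonconstant"))
    reports <- lapply(strategies, function(s)
      evaluate_separability(sub, s, n_splits = config$n_splits,
                            train_fraction = config$train_fraction,
                            seed = config$seed, ranking = ranking))
    rep_df <- data.frame(
      strategy = names(reports),
      k = vapply(reports, function(r)
        if (is.null(r$strategy$k)) NA_integer_ else r$strategy$k, integer(1)),
      test_mean = vapply(reports, `[[`, numeric(1), "test_mean"),
      test_sd = vapply(reports, `[[`, numeric(1), "test_sd"),
      train_mean = vapply(reports, `[[`, numeric(1), "train_mean"),
      misclassification = vapply(reports, `[[`, numeric(1),
                                 "mean_misclassification_rate"),
      row.names = NULL)
    data.table::fwrite(rep_df, file.path(out_dir, "classification_reports.csv"))

    list(qc_report = qc$report, embedding = prep$embedding,
         sweep = sweep_res, stratification = strat, mi_ranking = ranking,
         reports = reports)
  }, error = function(e) {
    manifest$error <<- list(stage = current_stage, message = conditionMessage(e))
    manifest$wall_clock_sec <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  manifest$config <- config_echo(config)
  manifest$argmax_p <- res$sweep$argmax_p
  manifest$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}

## flatten a RunConfig into plain nested lists for the JSON manifest
config_echo <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_echo) else unclass(x)
}
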