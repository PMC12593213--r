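#' Synthetic two-arm experiment configuration
#'
#' Parameters of the generative model the pipeline is validated against: an
#' untreated control arm that mixes a minority treatment-sensitive
#' subpopulation (fraction `sensitive_fraction`) with a majority resistant
#' subpopulation, and a treated arm drawn exclusively from the resistant
#' archetype — the survivor bias the stratification method is built to
#' exploit. The two archetypes differ on `n_signal_genes` genes whose means
#' are shifted by `log2_effect` (random sign per gene) in the sensitive
#' archetype. Counts are negative-binomial with log-normal per-cell library
#' sizes. Technical features (mitochondrial "MT-" genes and "CMO"
#' multiplexing tags) are appended so QC and feature filters can be
#' exercised.
#'
#' @param n_control,n_treated cells per arm (defaults 1000 and 400).
#' @param sensitive_fraction fraction of control cells drawn from the
#'   sensitive archetype, in \[0, 1\] (default 0.25).
#' @param n_genes biological genes (default 2000), excluding technical
#'   features.
#' @param n_signal_genes genes separating the archetypes (default 10).
#' @param log2_effect absolute log2 mean shift on signal genes (default 2).
#' @param n_treatment_shift_genes,treatment_log2_effect optional mild
#'   direct treatment effect applied to the treated arm only (defaults 0),
#'   for probing violations of the "treatment does not alter resistant
#'   cells" assumption.
#' @param dispersion negative-binomial size (inverse-dispersion) parameter
#'   (default 10, the mild overdispersion typical of UMI counts; smaller =
#'   noisier).
#' @param library_size_mean mean per-cell depth in counts (default
#'   15,000, a typical droplet-protocol depth for cultured cell lines).
#' @param library_size_shape sdlog of the log-normal depth distribution
#'   (default 0.35).
#' @param n_mito_genes mitochondrial genes, "MT-" prefixed (default 10);
#'   they carry ~5 % of each cell's expression mass.
#' @param n_cmo_features "CMO"-prefixed technical tags (default 4).
#' @param seed integer seed; generation is a pure function of the config.
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_control = 1000L, n_treated = 400L,
                             sensitive_fraction = 0.25, n_genes = 2000L,
                             n_signal_genes = 10L, log2_effect = 2,
                             n_treatment_shift_genes = 0L,
                             treatment_log2_effect = 0,
                             dispersion = 10, library_size_mean = 15000,
                             library_size_shape = 0.35,
                             n_mito_genes = 10L, n_cmo_features = 4L,
                             seed = 1L) {
  stopifnot(n_control >= 1, n_treated >= 1,
            sensitive_fraction >= 0, sensitive_fraction <= 1,
            n_signal_genes <= n_genes, n_treatment_shift_genes <= n_genes,
            dispersion > 0, library_size_mean > 0, library_size_shape > 0,
            n_mito_genes >= 0, n_cmo_features >= 0)
  structure(as.list(environment()), class = "SyntheticConfig")
}

#' Generate a synthetic labeled expression matrix with ground truth
#'
#' Draws the experiment described by a [synthetic_config()]: gene baseline
#' means are log-normal; the sensitive archetype multiplies signal-gene
#' means by `2^(+/- log2_effect)`; per-cell counts are
#' `NB(mu = depth * proportion, size = dispersion)` with log-normal depth.
#' The control arm holds `round(f * n_control)` sensitive cells (cell
#' order shuffled) with label 0; the treated arm holds `n_treated`
#' resistant-archetype cells with label 1, optionally shifted on the
#' treatment-shift genes. Mitochondrial genes are rescaled to carry ~5 %
#' of the expression mass; CMO tags carry ~0.5 %.
#'
#' @param config a [synthetic_config()].
#' @return A list with `matrix` (a [LabeledExpressionMatrix] of raw
#'   counts) and `truth` (class `GroundTruth`): `cells` (data.frame
#'   `cell_id`, `true_state`), `genes` (data.frame `gene_id`, `role` in
#'   signal / treatment_shift / mito / cmo / background), `config`.
#' @export
simulate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  ng <- config$n_genes
  gene_names <- sprintf("GENE%05d", seq_len(ng))
  mito_names <- if (config$n_mito_genes > 0)
    sprintf("MT-G%02d", seq_len(config$n_mito_genes)) else character(0)
  cmo_names <- if (config$n_cmo_features > 0)
    sprintf("CMO%03d", 300L + seq_len(config$n_cmo_features)) else character(0)

  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.5)
  # signal genes sit in the top expression decile: the discriminative
  # programs this method targets (proliferation / cell-cycle markers) are
  # well-expressed, and lowly expressed genes carry no usable signal at
  # single-cell depth
  n_high <- max(config$n_signal_genes, ceiling(0.1 * ng))
  high <- order(-base)[seq_len(min(n_high, ng))]
  signal <- sort(sample(high, config$n_signal_genes))
  sign_dir <- sample(c(-1, 1), config$n_signal_genes, replace = TRUE)
  sens_mean <- base
  sens_mean[signal] <- base[signal] * 2^(sign_dir * config$log2_effect)
  res_mean <- base

  trt_mean <- res_mean
  shift <- integer(0)
  if (config$n_treatment_shift_genes > 0) {
    shift <- sort(sample(setdiff(seq_len(ng), signal),
                         config$n_treatment_shift_genes))
    dir2 <- sample(c(-1, 1), length(shift), replace = TRUE)
    trt_mean[shift] <- res_mean[shift] * 2^(dir2 * config$treatment_log2_effect)
  }

  # technical blocks: mito ~5% of mass, CMO ~0.5%
  mito_w <- if (length(mito_names)) {
    w <- stats::rlnorm(length(mito_names), 0, 0.5)
    w / sum(w) * 0.05 / 0.945
  } else numeric(0)
  cmo_w <- if (length(cmo_names)) {
    w <- stats::rlnorm(length(cmo_names), 0, 0.5)
    w / sum(w) * 0.005 / 0.945
  } else numeric(0)

  archetype_props <- function(mu) {
    mu <- mu / sum(mu)                       # biological block sums to 1
    p <- c(mu, mito_w * sum(mu), cmo_w * sum(mu))
    p / sum(p)
  }
  p_sens <- archetype_props(sens_mean)
  p_res <- archetype_props(res_mean)
  p_trt <- archetype_props(trt_mean)

  n_sens <- round(config$sensitive_fraction * config$n_control)
  if (config$sensitive_fraction > 0 && n_sens == 0L)
    warning("sensitive_fraction rounds to zero sensitive cells")
  state <- sample(rep(c("sensitive", "resistant"),
                      c(n_sens, config$n_control - n_sens)))
  n_all <- config$n_control + config$n_treated
  depth <- stats::rlnorm(n_all,
                         meanlog = log(config$library_size_mean) -
                           config$library_size_shape^2 / 2,
                         sdlog = config$library_size_shape)

  all_names <- c(gene_names, mito_names, cmo_names)
  counts <- matrix(0, nrow = length(all_names), ncol = n_all)
  for (j in seq_len(n_all)) {
    p <- if (j <= config$n_control) {
      if (state[j] == "sensitive") p_sens else p_res
    } else p_trt
    counts[, j] <- stats::rnbinom(length(p), mu = depth[j] * p,
                                  size = config$dispersion)
  }
  cell_names <- c(sprintf("CTRL_%04d", seq_len(config$n_control)),
                  sprintf("TRT_%04d", seq_len(config$n_treated)))
  dimnames(counts) <- list(all_names, cell_names)
  labels <- rep(c(0L, 1L), c(config$n_control, config$n_treated))

  role <- rep("background", length(all_names))
  role[signal] <- "signal"
  role[shift] <- "treatment_shift"
  role[seq_along(mito_names) + ng] <- "mito"
  role[seq_along(cmo_names) + ng + length(mito_names)] <- "cmo"

  truth <- structure(
    list(cells = data.frame(cell_id = cell_names,
                            true_state = c(state, rep("resistant",
                                                      config$n_treated)),
                            stringsAsFactors = FALSE),
         genes = data.frame(gene_id = all_names, role = role,
                            stringsAsFactors = FALSE),
         config = config),
    class = "GroundTruth")
  list(matrix = LabeledExpressionMatrix(counts, labels),
       truth = truth)
}

#' Write generator ground truth as CSVs
#'
#' Emits `<prefix>_cells.csv` (cell_id, true_state) and
#' `<prefix>_genes.csv` (gene_id, role).
#'
#' @param truth a `GroundTruth`.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_ground_truth_csv <- function(truth, prefix) {
  p1 <- paste0(prefix, "_cells.csv")
  p2 <- paste0(prefix, "_genes.csv")
  data.table::fwrite(truth$cells, p1)
  data.table::fwrite(truth$genes, p2)
  invisible(c(p1, p2))
}
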