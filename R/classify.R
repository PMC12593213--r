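#' Gene-selection strategy for separability scoring
#'
#' The three strategies under which classifier performance is compared:
#' the `k` top genes of a mutual-information ranking, `k` genes drawn
#' uniformly at random, or all genes whose expression is not constant
#' across cells.
#'
#' @param kind `"top_mi"`, `"random"` or `"all_nonconstant"`.
#' @param k gene count (required for `top_mi` and `random`).
#' @param seed integer seed for the random draw.
#' @return An object of class `GeneSelectionStrategy`.
#' @export
gene_selection <- function(kind = c("top_mi", "random", "all_nonconstant"),
                           k = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("top_mi", "random")) {
    if (is.null(k) || k < 1) stop("strategy '", kind, "' requires k >= 1")
    k <- as.integer(k)
  }
  structure(list(kind = kind, k = k, seed = as.integer(seed)),
            class = "GeneSelectionStrategy")
}

#' Resolve a strategy to concrete gene ids
#'
#' @param strategy a [gene_selection()].
#' @param m the [LabeledExpressionMatrix] being classified.
#' @param ranking an `MIRanking` on `m` (required for `top_mi`; computed on
#'   the fly when missing).
#' @param binning a [binning_config()] used if a ranking must be computed.
#' @return Character vector of gene ids.
#' @export
strategy_genes <- function(strategy, m, ranking = NULL,
                           binning = binning_config()) {
  switch(strategy$kind,
    top_mi = {
      if (is.null(ranking)) ranking <- rank_genes_mi(m, binning)
      if (strategy$k > nrow(ranking)) stop("k exceeds available genes")
      top_mi_genes(ranking, strategy$k)
    },
    random = {
      if (strategy$k > nrow(m$counts)) stop("k exceeds available genes")
      set.seed(strategy$seed)
      sample(rownames(m$counts), strategy$k)
    },
    all_nonconstant = {
      v <- apply(m$counts, 1L, function(x) any(x != x[1L]))
      rownames(m$counts)[v]
    })
}

#' Balanced accuracy of a binary prediction
#'
#' `(sensitivity + specificity) / 2` from the confusion counts; chance
#' level is 0.5 for any class balance.
#'
#' @param true_labels,predicted_labels aligned 0/1 vectors; both classes
#'   must appear in `true_labels`.
#' @return Value in \[0, 1\].
#' @export
balanced_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (!all(true_labels %in% c(0, 1)) || !all(predicted_labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  if (length(unique(true_labels)) < 2L)
    stop("both classes must be present in true_labels")
  tpr <- mean(predicted_labels[true_labels == 1] == 1)
  tnr <- mean(predicted_labels[true_labels == 0] == 0)
  (tpr + tnr) / 2
}

## deterministic per-split seed fan-out from a master seed
split_seed <- function(seed, i) (as.integer(seed) + 7919L * i) %% .Machine$integer.max

#' Score group separability with a repeatedly-split MLP
#'
#' The package's measuring instrument for "how separable are these two
#' groups": over `n_splits` stratified random train/test splits
#' (`train_fraction` per class), features restricted to the strategy's gene
#' subset are z-scored on the training split (the same transform is applied
#' to the test split — no leakage), a feed-forward network (one hidden
#' layer of 100 rectified-linear units, logistic cross-entropy, Adam
#' optimizer, iteration cap 500 with improvement tolerance 1e-4) is fit,
#' and train/test balanced accuracies are recorded. Identical inputs and
#' master seed reproduce the report exactly.
#'
#' @param m a [LabeledExpressionMatrix]; expression is typically
#'   log-normalized. Both classes need at least 5 cells.
#' @param strategy a [gene_selection()].
#' @param n_splits number of random splits (default 20).
#' @param train_fraction fraction of each class used for training
#'   (default 0.8).
#' @param seed master seed; per-split seeds are derived from it.
#' @param ranking optional `MIRanking` for the `top_mi` strategy.
#' @param hidden,max_iter MLP size and iteration cap.
#' @return An object of class `ClassificationReport`: list with the
#'   strategy, per-split train/test balanced accuracies, `test_mean`,
#'   `test_sd`, `train_mean` and `mean_misclassification_rate`
#'   (`1 - test_mean`).
#' @export
evaluate_separability <- function(m, strategy, n_splits = 20L,
                                  train_fraction = 0.8, seed = 1L,
                                  ranking = NULL, hidden = 100L,
                                  max_iter = 500L) {
  y <- unname(m$labels)
  if (min(table(y)) < 5L) stop("each class needs at least 5 cells")
  genes <- strategy_genes(strategy, m, ranking)
  if (length(genes) == 0L) stop("strategy selected zero genes")
  X <- t(m$counts[genes, , drop = FALSE])  # cells x genes

  tr_acc <- te_acc <- numeric(n_splits)
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  n0 <- max(1L, round(train_fraction * length(i0)))
  n1 <- max(1L, round(train_fraction * length(i1)))
  for (s in seq_len(n_splits)) {
    set.seed(split_seed(seed, s))
    tr <- c(sample(i0, n0), sample(i1, n1))
    te <- setdiff(seq_along(y), tr)

    mu <- colMeans(X[tr, , drop = FALSE])
    sd_tr <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd_tr[sd_tr == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sd_tr, `/`)
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd_tr, `/`)

    fit <- mlp_train(Ztr, y[tr], hidden = hidden, max_iter = max_iter,
                     seed = split_seed(seed, s))
    tr_acc[s] <- balanced_accuracy(y[tr], mlp_predict(fit, Ztr))
    te_acc[s] <- balanced_accuracy(y[te], mlp_predict(fit, Zte))
  }
  structure(list(strategy = strategy, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 per_split_train_balanced_accuracy = tr_acc,
                 per_split_test_balanced_accuracy = te_acc,
                 train_mean = mean(tr_acc),
                 test_mean = mean(te_acc),
                 test_sd = stats::sd(te_acc),
                 mean_misclassification_rate = 1 - mean(te_acc)),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport [%s%s]: test %.4f +/- %.4f (train %.4f, %d splits)\n",
              x$strategy$kind,
              if (!is.null(x$strategy$k)) paste0(", k=", x$strategy$k) else "",
              x$test_mean, x$test_sd, x$train_mean, x$n_splits))
  invisible(x)
}

#' Default predicted-sensitive percentage grid
#'
#' 23 cutoffs: 2, 4, 6, 8, 10, then 15 to 100 in steps of 5.
#'
#' @return Numeric vector of length 23.
#' @export
default_p_grid <- function() c(2, 4, 6, 8, 10, seq(15, 100, by = 5))

#' Sweep the predicted-sensitive percentage
#'
#' For every cutoff `p` in the grid: stratify the control cells by their
#' similarity score, assemble a two-group matrix of predicted-sensitive
#' (label 0) versus treated (label 1) cells, and score separability with
#' [evaluate_separability()] on the z-scored expression of all
#' (non-constant) genes. The accuracy curve over `p` locates the cutoff at
#' which the predicted-sensitive set stops being homogeneous: accuracy sits
#' on a plateau while the set contains genuinely treatment-sensitive cells
#' and declines once resistant-like cells dilute it.
#'
#' @param m a [LabeledExpressionMatrix] holding classifier features
#'   (log-normalized expression) for all cells, labels 0 = control,
#'   1 = treated.
#' @param embedding an `EmbeddingResult` covering all cells of `m`.
#' @param dcfg a [distance_config()].
#' @param p_grid strictly increasing percentages in (0, 100\]
#'   (default [default_p_grid()]).
#' @param n_splits,train_fraction,seed,hidden,max_iter passed to
#'   [evaluate_separability()].
#' @return An object of class `SweepResult`: list with `p_grid`, `curve`
#'   (data.frame: `p`, `n_sensitive`, `valid`, `test_mean`, `test_sd`,
#'   `train_mean`), `reports` (per-p `ClassificationReport`s) and
#'   `argmax_p` (grid value with the highest `test_mean`; ties take the
#'   smallest p). Grid points yielding a predicted-sensitive class of
#'   fewer than 5 cells are marked invalid, not fatal.
#' @export
sensitivity_sweep <- function(m, embedding, dcfg = distance_config(),
                              p_grid = default_p_grid(), n_splits = 20L,
                              train_fraction = 0.8, seed = 1L,
                              hidden = 100L, max_iter = 500L) {
  if (any(p_grid <= 0 | p_grid > 100) || is.unsorted(p_grid, strictly = TRUE))
    stop("p_grid must be strictly increasing within (0, 100]")
  ctrl <- names(m$labels)[m$labels == 0L]
  trt <- names(m$labels)[m$labels == 1L]
  D <- pairwise_distances(embedding, ctrl, trt, dcfg$metric)
  scores <- similarity_scores(D, dcfg$aggregation)

  reports <- vector("list", length(p_grid))
  rows <- lapply(seq_along(p_grid), function(i) {
    p <- p_grid[i]
    strat <- suppressWarnings(stratify_cells(scores, p))
    sens <- predicted_sensitive(strat)
    if (length(sens) < 5L)
      return(data.frame(p = p, n_sensitive = length(sens), valid = FALSE,
                        test_mean = NA_real_, test_sd = NA_real_,
                        train_mean = NA_real_))
    sub <- subset_cells(m, c(sens, trt))
    rep_i <- evaluate_separability(sub, gene_selection("all_nonconstant"),
                                   n_splits = n_splits,
                                   train_fraction = train_fraction,
                                   seed = split_seed(seed, as.integer(round(100 * p))),
                                   hidden = hidden, max_iter = max_iter)
    reports[[i]] <<- rep_i
    data.frame(p = p, n_sensitive = length(sens), valid = TRUE,
               test_mean = rep_i$test_mean, test_sd = rep_i$test_sd,
               train_mean = rep_i$train_mean)
  })
  curve <- do.call(rbind, rows)
  valid <- which(curve$valid)
  argmax <- if (length(valid)) curve$p[valid[which.max(curve$test_mean[valid])]]
            else NA_real_
  structure(list(p_grid = p_grid, curve = curve, reports = reports,
                 scores = scores, argmax_p = argmax),
            class = "SweepResult")
}

#' @export
print.SweepResult <- function(x, ...) {
  cat(sprintf("SweepResult over %d cutoffs; argmax_p = %s\n",
              length(x$p_grid), format(x$argmax_p)))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Write a sweep curve as CSV
#'
#' Columns: `p`, `n_sensitive`, `valid`, `test_mean`, `test_sd`,
#' `train_mean`.
#'
#' @param sweep a `SweepResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  data.table::fwrite(sweep$curve, path)
  invisible(path)
}
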