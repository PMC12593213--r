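#' Preprocessing configuration
#'
#' Parameters of the chain that defines the distance space: per-cell library
#' size normalization to `target_sum` counts, log1p transform, selection of
#' `n_hvg` highly variable genes, per-gene scaling to unit variance, and PCA
#' to `n_components` dimensions.
#'
#' @param target_sum per-cell count total after normalization (default
#'   10,000).
#' @param n_hvg number of highly variable genes (default 2,000).
#' @param n_components PCA dimensionality (default 30).
#' @param scale_clip optional absolute cap applied to scaled values
#'   (default `NULL`, no clipping).
#' @param restrict_pca_to_hvg if `TRUE` (default) PCA runs on the HVG
#'   subset; otherwise on all genes.
#' @return An object of class `PreprocessConfig`.
#' @export
preprocess_config <- function(target_sum = 1e4, n_hvg = 2000L,
                              n_components = 30L, scale_clip = NULL,
                              restrict_pca_to_hvg = TRUE) {
  stopifnot(target_sum > 0, n_hvg >= 1, n_components >= 1,
            is.null(scale_clip) || scale_clip > 0)
  structure(list(target_sum = target_sum, n_hvg = as.integer(n_hvg),
                 n_components = as.integer(n_components),
                 scale_clip = scale_clip,
                 restrict_pca_to_hvg = isTRUE(restrict_pca_to_hvg)),
            class = "PreprocessConfig")
}

#' Library-size normalization
#'
#' Rescales every cell so its column sums to `target_sum`, preserving
#' within-cell proportions.
#'
#' @param m a [LabeledExpressionMatrix]; every cell must have total > 0
#'   (guaranteed after QC filtering).
#' @param target_sum positive target total per cell.
#' @return The normalized [LabeledExpressionMatrix].
#' @export
normalize_total <- function(m, target_sum = 1e4) {
  stopifnot(target_sum > 0)
  total <- colSums(m$counts)
  if (any(total == 0))
    stop("cell with zero total count (should have been QC-filtered): ",
         colnames(m$counts)[which(total == 0)[1L]])
  m$counts <- sweep(m$counts, 2L, target_sum / total, `*`)
  m
}

#' Elementwise log(1 + x) transform
#'
#' @param m a [LabeledExpressionMatrix] with non-negative values.
#' @return The transformed [LabeledExpressionMatrix].
#' @export
log1p_transform <- function(m) {
  if (any(m$counts < 0)) stop("log1p_transform requires non-negative values")
  m$counts <- log1p(m$counts)
  m
}

#' Select highly variable genes (vst flavor)
#'
#' Ranks genes by standardized variance computed on raw counts, in the
#' Seurat-v3 manner: per-gene mean and variance, a loess fit (span 0.3) of
#' log10(variance) on log10(mean) giving each gene an expected standard
#' deviation, standardization of counts by `(x - mean) / expected_sd` with
#' values clipped above at `sqrt(n_cells)`, and ranking by the variance of
#' the clipped standardized values (computed about the unclipped gene
#' mean). Zero-variance genes get standardized variance 0. Ties are broken
#' by gene id so the selection is deterministic.
#'
#' @param m a [LabeledExpressionMatrix] of raw counts with at least 2 cells.
#' @param n_hvg number of genes to return.
#' @return Character vector of `n_hvg` gene ids, highest standardized
#'   variance first.
#' @export
select_hvg <- function(m, n_hvg = 2000L) {
  x <- m$counts
  n <- ncol(x)
  if (n < 2L) stop("select_hvg requires at least 2 cells")
  if (n_hvg > nrow(x)) stop("n_hvg exceeds the number of genes")
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  if (n_hvg > sum(v > 0))
    stop("n_hvg exceeds the number of genes with nonzero variance")

  std_var <- numeric(nrow(x))
  use <- v > 0 & mu > 0
  fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = 0.3,
                      degree = 2, family = "gaussian")
  esd <- sqrt(10^stats::fitted(fit))
  clip_max <- sqrt(n)
  xu <- x[use, , drop = FALSE]
  z <- (xu - mu[use]) / esd
  z <- pmin(z, clip_max)
  # variance of clipped standardized values about the (unclipped) gene mean
  std_var[use] <- rowSums(z^2) / (n - 1)

  ord <- order(-std_var, rownames(x))
  rownames(x)[ord][seq_len(n_hvg)]
}

#' Scale genes to zero mean and unit variance
#'
#' Standardizes each gene row with population (ddof 0) variance; constant
#' genes become all-zero rows. With `clip` set, standardized values are
#' truncated to `[-clip, clip]`.
#'
#' @param m a [LabeledExpressionMatrix] (conventionally log-normalized).
#' @param clip optional positive clipping bound.
#' @return The scaled [LabeledExpressionMatrix].
#' @export
scale_unit_variance <- function(m, clip = NULL) {
  x <- m$counts
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  x <- (x - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  x[sd_pop == 0, ] <- 0
  if (!is.null(clip)) {
    stopifnot(clip > 0)
    x <- pmin(pmax(x, -clip), clip)
  }
  m$counts <- x
  m
}

#' PCA embedding of cells
#'
#' Exact-SVD principal component analysis of the cells-by-genes matrix
#' (genes centered; no further scaling — scale beforehand with
#' [scale_unit_variance()]). The sign of each component is fixed so that
#' its largest-magnitude gene loading is positive, making results
#' reproducible across platforms.
#'
#' @param m a [LabeledExpressionMatrix] (conventionally scaled).
#' @param config a [preprocess_config()]; only `n_components` is used here.
#' @param genes optional gene ids to restrict to (e.g. HVGs); default all.
#' @return An object of class `EmbeddingResult`: list with `cell_ids`,
#'   `coordinates` (cells x n_components, rownames = cell ids),
#'   `explained_variance_ratio`, `gene_loadings` (genes-used x
#'   n_components) and `genes_used`.
#' @export
pca_embed <- function(m, config = preprocess_config(), genes = NULL) {
  if (!is.null(genes)) m <- subset_genes(m, genes)
  k <- config$n_components
  X <- t(m$counts)  # cells x genes
  if (k > min(nrow(X) - 1L, ncol(X)))
    stop("n_components exceeds min(n_cells - 1, n_genes used)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  # sign convention: largest-|loading| per component positive
  flip <- apply(pc$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(cell_ids = rownames(X),
                 coordinates = coords,
                 explained_variance_ratio = evr[seq_len(k)],
                 gene_loadings = loadings,
                 genes_used = colnames(X)),
            class = "EmbeddingResult")
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat(sprintf("EmbeddingResult: %d cells x %d components (%.1f%% variance)\n",
              length(x$cell_ids), ncol(x$coordinates),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Write / read cell embeddings as CSV
#'
#' The CSV has a `cell_id` column followed by one column per dimension.
#' [read_embedding_csv()] accepts any such file, so externally computed
#' coordinates (t-SNE, UMAP, ...) can be substituted as the distance space
#' of [pairwise_distances()]; fields other than `cell_ids` and
#' `coordinates` are then empty.
#'
#' @param emb an `EmbeddingResult`.
#' @param path CSV path.
#' @return `path` (write) or an `EmbeddingResult` (read).
#' @export
write_embedding_csv <- function(emb, path) {
  dt <- data.table::data.table(cell_id = emb$cell_ids, emb$coordinates)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  stopifnot("cell_id" %in% names(dt))
  coords <- as.matrix(dt[, setdiff(names(dt), "cell_id"), with = FALSE])
  rownames(coords) <- dt$cell_id
  structure(list(cell_ids = dt$cell_id, coordinates = coords,
                 explained_variance_ratio = NULL,
                 gene_loadings = NULL, genes_used = NULL),
            class = "EmbeddingResult")
}

#' Run the full preprocessing chain
#'
#' QC-filtered raw counts in, embedding out: normalize to `target_sum`,
#' log1p, select HVGs on the raw counts, scale to unit variance, PCA.
#'
#' @param m a [LabeledExpressionMatrix] of raw counts (post-QC, technical
#'   features removed).
#' @param config a [preprocess_config()].
#' @return A list with `embedding` (an `EmbeddingResult`), `lognorm` (the
#'   log-normalized matrix, used downstream as classifier/MI feature space)
#'   and `hvg` (the selected gene ids).
#' @export
preprocess <- function(m, config = preprocess_config()) {
  hvg <- select_hvg(m, min(config$n_hvg, nrow(m$counts)))
  ln <- log1p_transform(normalize_total(m, config$target_sum))
  sc <- scale_unit_variance(ln, clip = config$scale_clip)
  emb <- pca_embed(sc, config,
                   genes = if (config$restrict_pca_to_hvg) hvg else NULL)
  list(embedding = emb, lognorm = ln, hvg = hvg)
}
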