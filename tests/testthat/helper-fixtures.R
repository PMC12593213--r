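# Small in-code fixtures shared across test files.

# genes x cells matrix with names; values supplied column-wise
lem <- function(values, n_genes, n_cells, labels,
                gene_ids = sprintf("g%02d", seq_len(n_genes)),
                cell_ids = sprintf("c%02d", seq_len(n_cells))) {
  LabeledExpressionMatrix(
    matrix(values, n_genes, n_cells, dimnames = list(gene_ids, cell_ids)),
    labels = labels)
}

# random count fixture, reproducible
random_lem <- function(n_genes, n_cells, seed = 1L,
                       labels = rep(c(0L, 1L), length.out = n_cells)) {
  set.seed(seed)
  lem(rpois(n_genes * n_cells, 20) + 1, n_genes, n_cells, labels)
}

# brute-force distance oracles, independent of the package implementation
cosine_oracle <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
euclid_oracle <- function(u, v) sqrt(sum((u - v)^2))

# plug-in MI oracle: direct summation over the joint table
mi_oracle <- function(x, y, base = 2) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pxy <- tab[i, j] / n
    if (pxy > 0) {
      px <- sum(tab[i, ]) / n
      py <- sum(tab[, j]) / n
      mi <- mi + pxy * log(pxy / (px * py), base = base)
    }
  }
  mi
}

# quick embedding wrapper around a coordinate matrix
coords_embedding <- function(coords) {
  structure(list(cell_ids = rownames(coords), coordinates = coords),
            class = "EmbeddingResult")
}

# crafted 5-cell QC fixture for thresholds 800 / 500 / 10%:
#   cell A: total 801 but only 1 gene detected       -> fails genes
#   cell B: total exactly 800 (boundary)             -> fails total (strict)
#   cell C: mitochondrial fraction above 10%         -> fails mito
#   cells D, E: compliant                            -> pass
qc_fixture <- function() {
  n_bio <- 600
  counts <- matrix(0, n_bio + 1, 5,
                   dimnames = list(c(sprintf("G%03d", seq_len(n_bio)), "MT-X"),
                                   c("A", "B", "C", "D", "E")))
  counts[1, "A"] <- 801
  counts[seq_len(550), "B"] <- 1; counts[1, "B"] <- 251      # total 800, 550 genes
  counts[seq_len(550), "C"] <- 1; counts[551, "C"] <- 351
  counts["MT-X", "C"] <- 101                                  # 101/1002 > 10%
  counts[seq_len(550), "D"] <- 2                               # total 1100
  counts[seq_len(560), "E"] <- 2; counts["MT-X", "E"] <- 50    # mito 50/1170 < 0.1
  LabeledExpressionMatrix(counts, labels = c(0L, 0L, 0L, 1L, 1L))
}
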