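#' Discretization settings for mutual-information estimation
#'
#' @param min_n_datapoints_a_bin minimum number of cells any expression bin
#'   may contain (default 50).
#' @param log_base logarithm base for MI (default 2, i.e. bits).
#' @return An object of class `BinningConfig`.
#' @export
binning_config <- function(min_n_datapoints_a_bin = 50L, log_base = 2) {
  stopifnot(min_n_datapoints_a_bin >= 1, log_base > 1)
  structure(list(min_n_datapoints_a_bin = as.integer(min_n_datapoints_a_bin),
                 log_base = log_base),
            class = "BinningConfig")
}

#' Equal-frequency discretization with a minimum-occupancy floor
#'
#' Bins one gene's per-cell expression into contiguous (in expression
#' order) bins: `k = floor(n / min_n_datapoints_a_bin)` initial
#' equal-frequency quantile cuts, with each cut pushed right so identical
#' expression values always share a bin, then adjacent bins merged (a
#' deficient bin into its right neighbor, the last into its left) until
#' every bin holds at least `min_n_datapoints_a_bin` cells. With fewer than
#' `min_n_datapoints_a_bin` cells the result is a single bin (with a
#' warning), so MI downstream is 0. Depending only on the ordering of
#' values, the binning — and hence MI — is invariant to strictly monotone
#' transformations of expression.
#'
#' @param values numeric vector of one gene's expression across cells.
#' @param config a [binning_config()].
#' @return Integer vector of 1-based bin indices, one per cell, with
#'   attribute `n_bins`.
#' @export
discretize_gene <- function(values, config = binning_config()) {
  n <- length(values)
  m <- config$min_n_datapoints_a_bin
  if (n < m) {
    warning("fewer cells than min_n_datapoints_a_bin; using a single bin")
    return(structure(rep(1L, n), n_bins = 1L))
  }
  k <- max(1L, n %/% m)
  sv <- sort(values)
  # boundary after sorted position floor(i*n/k), extended through ties
  cuts <- unique(as.integer(seq_len(k - 1L) * n %/% k))
  cuts <- vapply(cuts, function(b) {
    while (b < n && sv[b + 1L] == sv[b]) b <- b + 1L
    b
  }, integer(1L))
  cuts <- unique(cuts[cuts < n])
  breaks <- sv[cuts]  # break value = maximum of its bin

  # bin index = 1 + number of break values strictly below the value,
  # so ties at a break stay in the lower bin
  bins <- if (length(breaks)) 1L + rowSums(outer(values, breaks, `>`)) else rep(1L, n)

  # merge pass: any bin below the occupancy floor absorbs into a neighbor
  repeat {
    tab <- tabulate(bins, nbins = length(breaks) + 1L)
    deficient <- which(tab < m)
    if (length(deficient) == 0L || length(breaks) == 0L) break
    j <- deficient[1L]
    drop <- if (j <= length(breaks)) j else j - 1L  # merge right, last merges left
    breaks <- breaks[-drop]
    bins <- if (length(breaks)) 1L + rowSums(outer(values, breaks, `>`)) else rep(1L, n)
  }
  structure(as.integer(bins), n_bins = length(breaks) + 1L)
}

#' Plug-in mutual information between bins and binary labels
#'
#' Empirical (plug-in) MI over the joint distribution of bin index and
#' label: `sum p(x,y) log[p(x,y) / (p(x) p(y))]`, with zero-probability
#' cells contributing 0. Non-negative by construction; 0 when either
#' variable is constant.
#'
#' @param bins integer bin indices per cell.
#' @param labels 0/1 labels per cell, aligned with `bins`.
#' @param log_base logarithm base (default 2, giving bits).
#' @return Non-negative MI value.
#' @export
mutual_information <- function(bins, labels, log_base = 2) {
  if (length(bins) != length(labels)) stop("bins and labels length mismatch")
  joint <- table(bins, labels)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  mi <- sum(terms[p > 0]) / log(log_base)
  max(mi, 0)
}

#' Rank genes by mutual information with the group labels
#'
#' Discretizes every gene with [discretize_gene()] and scores its plug-in
#' MI with the 0/1 labels. Constant genes are kept with MI 0 and flagged,
#' so rankings have stable length and downstream "all non-constant genes"
#' selection can exclude them. Sorted by decreasing MI, ties by gene id.
#'
#' @param m a [LabeledExpressionMatrix]; both label groups must be
#'   non-empty. Expression may be on any scale — the ranking only uses
#'   within-gene value order.
#' @param config a [binning_config()].
#' @return An object of class `MIRanking`: a data.frame with columns
#'   `rank`, `gene_id`, `mi` (in bits for the default base), `n_bins`,
#'   `constant`.
#' @export
rank_genes_mi <- function(m, config = binning_config()) {
  if (length(unique(m$labels)) < 2L)
    stop("both label groups must be non-empty")
  res <- apply(m$counts, 1L, function(v) {
    const <- all(v == v[1L])
    b <- discretize_gene(v, config)
    c(mi = mutual_information(b, m$labels, config$log_base),
      n_bins = attr(b, "n_bins"), constant = as.numeric(const))
  })
  out <- data.frame(gene_id = rownames(m$counts),
                    mi = res["mi", ], n_bins = as.integer(res["n_bins", ]),
                    constant = res["constant", ] > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$mi, out$gene_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("MIRanking", "data.frame"))
}

#' Top genes of an MI ranking
#'
#' @param ranking an `MIRanking`.
#' @param k how many genes.
#' @return Character vector of the `k` top-ranked gene ids.
#' @export
top_mi_genes <- function(ranking, k) {
  stopifnot(k >= 1, k <= nrow(ranking))
  ranking$gene_id[seq_len(k)]
}

#' Write an MI ranking as CSV
#'
#' Columns: `rank`, `gene_id`, `mi_bits`, `n_bins`.
#'
#' @param ranking an `MIRanking`.
#' @param path output path.
#' @param top_k optionally restrict to the first `top_k` rows.
#' @return `path`, invisibly.
#' @export
write_mi_ranking_csv <- function(ranking, path, top_k = NULL) {
  dt <- data.table::data.table(rank = ranking$rank, gene_id = ranking$gene_id,
                               mi_bits = ranking$mi, n_bins = ranking$n_bins)
  if (!is.null(top_k)) dt <- dt[seq_len(min(top_k, nrow(dt)))]
  data.table::fwrite(dt, path)
  invisible(path)
}
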