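#' Labeled expression matrix
#'
#' The pipeline's universal currency: a dense genes-by-cells expression
#' matrix plus a binary group label per cell. On ingest the values are raw
#' counts; downstream stages (normalization, log transform, scaling) return
#' new objects of the same class with transformed values.
#'
#' @param counts numeric matrix, genes in rows and cells in columns, with
#'   unique rownames (gene ids) and unique colnames (cell ids). All values
#'   must be finite and non-negative.
#' @param labels integer vector of 0/1 group labels, one per cell, in column
#'   order (0 is conventionally the untreated control arm, 1 the treated
#'   arm).
#' @param label_names named character vector mapping the two codes to group
#'   names, e.g. `c("0" = "control", "1" = "treated")`.
#'
#' @return An object of class `LabeledExpressionMatrix`: a list with
#'   elements `counts` (the matrix), `labels` (named integer vector, names =
#'   cell ids) and `label_names`.
#' @export
#' @examples
#' m <- LabeledExpressionMatrix(
#'   matrix(rpois(12, 5), 3, 4,
#'          dimnames = list(paste0("g", 1:3), paste0("c", 1:4))),
#'   labels = c(0L, 0L, 1L, 1L))
#' n_cells(m)
LabeledExpressionMatrix <- function(counts, labels,
                                    label_names = c("0" = "control", "1" = "treated")) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell id: ", colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and non-negative")
  labels <- as.integer(labels)
  if (length(labels) != ncol(counts))
    stop("`labels` must have one entry per cell")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must all be 0 or 1")
  names(labels) <- colnames(counts)
  structure(list(counts = counts, labels = labels,
                 label_names = label_names),
            class = "LabeledExpressionMatrix")
}

#' @rdname LabeledExpressionMatrix
#' @param m a `LabeledExpressionMatrix`.
#' @export
gene_ids <- function(m) rownames(m$counts)

#' @rdname LabeledExpressionMatrix
#' @export
cell_ids <- function(m) colnames(m$counts)

#' @rdname LabeledExpressionMatrix
#' @export
n_genes <- function(m) nrow(m$counts)

#' @rdname LabeledExpressionMatrix
#' @export
n_cells <- function(m) ncol(m$counts)

#' @export
print.LabeledExpressionMatrix <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0L, 1L)))
  cat(sprintf("LabeledExpressionMatrix: %d genes x %d cells (%s: %d, %s: %d)\n",
              nrow(x$counts), ncol(x$counts),
              x$label_names[["0"]], tab[["0"]],
              x$label_names[["1"]], tab[["1"]]))
  invisible(x)
}

#' Subset a labeled matrix by cells or genes
#'
#' Keeps counts, labels and identifiers in lock-step. Character vectors are
#' matched against cell/gene ids (unknown ids error); integer vectors are
#' positional. The result preserves the order of `cells` / `genes`, which
#' is how predicted-sensitive and treated cells are recombined for
#' downstream comparisons.
#'
#' @param m a [LabeledExpressionMatrix].
#' @param cells,genes character ids or integer indices to keep.
#' @return The subsetted [LabeledExpressionMatrix].
#' @export
subset_cells <- function(m, cells) {
  keep <- if (is.character(cells)) match(cells, colnames(m$counts)) else cells
  if (is.character(cells) && anyNA(keep))
    stop("unknown cell id: ", cells[which(is.na(keep))[1L]])
  m$counts <- m$counts[, keep, drop = FALSE]
  m$labels <- m$labels[keep]
  m
}

#' @rdname subset_cells
#' @export
subset_genes <- function(m, genes) {
  keep <- if (is.character(genes)) match(genes, rownames(m$counts)) else genes
  if (is.character(genes) && anyNA(keep))
    stop("unknown gene id: ", genes[which(is.na(keep))[1L]])
  m$counts <- m$counts[keep, , drop = FALSE]
  m
}
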