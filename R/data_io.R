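#' Read a labeled expression CSV
#'
#' Reads the gene-by-cell CSV dialect used throughout the pipeline: gene
#' identifiers in the first column, one column per cell, and the binary
#' group labels (0 = control, 1 = treated) encoded in a dedicated row at the
#' top of the file. Two layouts are accepted and auto-detected:
#'
#' * canonical (what [write_labeled_csv()] emits): a header line of cell ids
#'   under a `gene_id` corner token, then the label row under a `label`
#'   corner token, then one row per gene;
#' * headerless: the label row is the literal first line; cell ids are then
#'   synthesized as `cell_0001`, `cell_0002`, ...
#'
#' @param path path to a CSV file.
#' @return A [LabeledExpressionMatrix] whose cell order is the file's column
#'   order.
#' @export
read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2L) stop("format error: file has fewer than 2 rows")
  if (length(unique(nf)) != 1L)
    stop("format error: ragged row at line ", which(nf != nf[1L])[1L])

  head2 <- readLines(path, n = 2L)
  f1 <- strsplit(head2[1L], ",", fixed = TRUE)[[1L]]
  v1 <- suppressWarnings(as.numeric(f1[-1L]))
  has_header <- anyNA(v1) || !all(v1 %in% c(0, 1))

  if (has_header) {
    cell_names <- f1[-1L]
    f2 <- strsplit(head2[2L], ",", fixed = TRUE)[[1L]]
    lab <- suppressWarnings(as.numeric(f2[-1L]))
    skip <- 2L
  } else {
    cell_names <- sprintf("cell_%04d", seq_len(nf[1L] - 1L))
    lab <- v1
    skip <- 1L
  }
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad))
    stop("format error: non-binary group label in column ", cell_names[bad[1L]])

  dt <- data.table::fread(path, skip = skip, header = FALSE, sep = ",",
                          colClasses = c("character", rep("numeric", nf[1L] - 1L)))
  gene_names <- dt[[1L]]
  if (anyDuplicated(gene_names))
    stop("format error: duplicate gene id ",
         gene_names[duplicated(gene_names)][1L])
  counts <- as.matrix(dt[, -1L])
  dimnames(counts) <- list(gene_names, cell_names)
  LabeledExpressionMatrix(counts, as.integer(lab))
}

#' Write a labeled expression CSV
#'
#' Emits the canonical form of the labeled CSV dialect: a `gene_id` header
#' row carrying the cell ids, a `label` row carrying the 0/1 group labels,
#' then one row per gene. `read_labeled_csv(write_labeled_csv(m))`
#' reproduces gene ids, cell ids and labels exactly and values to full
#' stored precision.
#'
#' @param m a [LabeledExpressionMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(m, path) {
  writeLines(c(paste(c("gene_id", colnames(m$counts)), collapse = ","),
               paste(c("label", m$labels), collapse = ",")), path)
  body <- data.table::data.table(gene_id = rownames(m$counts), m$counts)
  data.table::fwrite(body, path, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Cell quality-control thresholds
#'
#' All three criteria are strict inequalities: a cell is retained only if
#' its total count is strictly greater than `min_total_counts`, the number
#' of detected genes (count > 0) is strictly greater than
#' `min_genes_detected`, and its mitochondrial fraction is strictly below
#' `max_mito_fraction`. Defaults follow the standard single-cell QC rule of
#' total counts > 800, detected genes > 500 and < 10 % mitochondrial reads,
#' with mitochondrial genes identified by the human "MT-" symbol prefix.
#'
#' @param min_total_counts exclusive lower bound on per-cell total counts.
#' @param min_genes_detected exclusive lower bound on detected genes.
#' @param max_mito_fraction exclusive upper bound on mitochondrial fraction,
#'   in \[0, 1\].
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return An object of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_total_counts = 800,
                          min_genes_detected = 500,
                          max_mito_fraction = 0.10,
                          mito_prefix = "MT-") {
  stopifnot(is.finite(min_total_counts), is.finite(min_genes_detected),
            is.finite(max_mito_fraction),
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            is.character(mito_prefix), nzchar(mito_prefix))
  structure(list(min_total_counts = min_total_counts,
                 min_genes_detected = min_genes_detected,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "QCThresholds")
}

#' Drop technical features by gene-id prefix
#'
#' Removes rows whose gene id starts with any of the given prefixes —
#' typically multiplexing tags ("CMO...") that are technical identifiers,
#' not genes. Zero matches is a no-op; the cell set is never changed.
#'
#' @param m a [LabeledExpressionMatrix].
#' @param prefixes non-empty character vector of prefixes (default `"CMO"`).
#' @return The filtered [LabeledExpressionMatrix].
#' @export
drop_technical_features <- function(m, prefixes = "CMO") {
  if (length(prefixes) == 0L || !is.character(prefixes) || any(!nzchar(prefixes)))
    stop("`prefixes` must be a non-empty character vector")
  pat <- paste0("^(", paste(sapply(prefixes, rex_escape), collapse = "|"), ")")
  keep <- !grepl(pat, rownames(m$counts))
  subset_genes(m, which(keep))
}

rex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Filter cells by quality-control criteria
#'
#' Computes per-cell total counts, detected genes (entries > 0) and
#' mitochondrial count fraction, and retains the cells passing all three
#' strict-inequality thresholds (see [qc_thresholds()]). A cell with total
#' count 0 fails (its mitochondrial fraction is reported as `NaN`, never a
#' division error). Survivors' columns are returned unmodified, so the
#' filter is idempotent. Run this on the full raw matrix, before removing
#' technical features, so mitochondrial fractions use the complete
#' denominator.
#'
#' @param m a [LabeledExpressionMatrix] of raw counts.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `matrix` (the filtered
#'   [LabeledExpressionMatrix]) and `report`, a data.frame with columns
#'   `cell_id`, `total_counts`, `genes_detected`, `mito_fraction`, `passed`
#'   and `fail_reasons` (`;`-separated, empty when passed).
#' @export
qc_filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  total <- colSums(m$counts)
  detected <- colSums(m$counts > 0)
  is_mito <- startsWith(rownames(m$counts), thresholds$mito_prefix)
  mito <- if (any(is_mito)) colSums(m$counts[is_mito, , drop = FALSE]) else
    rep(0, ncol(m$counts))
  mito_frac <- mito / total  # NaN for empty cells; comparisons below are NA-safe

  fail_total <- !(total > thresholds$min_total_counts)
  fail_genes <- !(detected > thresholds$min_genes_detected)
  fail_mito <- !(is.finite(mito_frac) & mito_frac < thresholds$max_mito_fraction)
  passed <- !(fail_total | fail_genes | fail_mito)

  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "low_total_counts", if (b) "low_genes_detected",
            if (c) "high_mito_fraction"), collapse = ";")
  }, fail_total, fail_genes, fail_mito)

  report <- data.frame(cell_id = colnames(m$counts),
                       total_counts = unname(total),
                       genes_detected = unname(detected),
                       mito_fraction = unname(mito_frac),
                       passed = unname(passed),
                       fail_reasons = unname(reasons),
                       stringsAsFactors = FALSE)
  list(matrix = subset_cells(m, which(passed)), report = report)
}

#' Write a per-cell QC report as CSV
#'
#' @param report the `report` element of [qc_filter_cells()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(report, path)
  invisible(path)
}
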