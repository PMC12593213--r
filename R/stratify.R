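#' Distance configuration
#'
#' @param metric distance between cells in the embedding: `"cosine"`
#'   (default) or `"euclidean"`.
#' @param aggregation how a control cell's distances to the whole treated
#'   set collapse to one similarity score: `"min"` (default) or `"mean"`.
#' @return An object of class `DistanceConfig`.
#' @export
distance_config <- function(metric = c("cosine", "euclidean"),
                            aggregation = c("min", "mean")) {
  structure(list(metric = match.arg(metric),
                 aggregation = match.arg(aggregation)),
            class = "DistanceConfig")
}

#' Control-to-treated pairwise distances
#'
#' Dense distance matrix between every control cell and every treated cell
#' in an embedding space. Cosine distance is `1 - u.v / (|u||v|)` (range
#' \[0, 2\]); euclidean is the usual `|u - v|`.
#'
#' @param emb an `EmbeddingResult` (or anything with `coordinates` rownamed
#'   by cell id).
#' @param control_ids,treated_ids disjoint cell-id vectors, all present in
#'   the embedding.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return Numeric matrix, controls in rows, treated in columns, dimnames
#'   set to the ids.
#' @export
pairwise_distances <- function(emb, control_ids, treated_ids,
                               metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  X <- emb$coordinates
  miss <- setdiff(c(control_ids, treated_ids), rownames(X))
  if (length(miss)) stop("unknown cell id: ", miss[1L])
  if (length(intersect(control_ids, treated_ids)))
    stop("control and treated sets overlap")
  U <- X[control_ids, , drop = FALSE]
  V <- X[treated_ids, , drop = FALSE]
  if (metric == "cosine") {
    nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
    if (any(nu == 0)) stop("zero-norm coordinates for cell ",
                           control_ids[which(nu == 0)[1L]])
    if (any(nv == 0)) stop("zero-norm coordinates for cell ",
                           treated_ids[which(nv == 0)[1L]])
    D <- 1 - (U %*% t(V)) / outer(nu, nv)
    D[D < 0] <- 0  # guard tiny negative round-off
  } else {
    # |u-v|^2 = |u|^2 + |v|^2 - 2 u.v
    D2 <- outer(rowSums(U^2), rowSums(V^2), `+`) - 2 * (U %*% t(V))
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
  }
  dimnames(D) <- list(control_ids, treated_ids)
  D
}

#' Per-control similarity scores
#'
#' Collapses each control cell's row of distances to the treated set into a
#' single score: the minimal (default) or mean distance. Lower score means
#' more similar to the treated survivors.
#'
#' @param D a control x treated distance matrix from
#'   [pairwise_distances()].
#' @param aggregation `"min"` or `"mean"`.
#' @return Named numeric vector of scores (names = control cell ids).
#' @export
similarity_scores <- function(D, aggregation = c("min", "mean")) {
  aggregation <- match.arg(aggregation)
  if (!is.matrix(D) || ncol(D) == 0L || nrow(D) == 0L)
    stop("empty distance matrix (no treated or no control cells)")
  s <- if (aggregation == "min") apply(D, 1L, min) else rowMeans(D)
  stats::setNames(s, rownames(D))
}

#' Stratify control cells at a cutoff percentage
#'
#' Ranks control cells from most to least dissimilar to the treated set
#' (rank 1 = highest score = most dissimilar; ties broken by cell id
#' ascending) and labels the top `floor(p_sensitive/100 * n)` cells
#' `predicted_sensitive`, the rest `predicted_resistant`. If the floor is
#' zero the result carries no sensitive cells and its `warning_empty`
#' attribute is `TRUE`.
#'
#' @param scores named numeric vector from [similarity_scores()].
#' @param p_sensitive percentage in (0, 100\].
#' @return An object of class `StratificationResult`: a data.frame with
#'   columns `cell_id`, `score`, `rank` and `label`, ordered by rank, with
#'   attributes `p_sensitive` and `warning_empty`.
#' @export
stratify_cells <- function(scores, p_sensitive) {
  if (!is.numeric(p_sensitive) || length(p_sensitive) != 1L ||
      p_sensitive <= 0 || p_sensitive > 100)
    stop("p_sensitive must be in (0, 100]")
  n <- length(scores)
  ord <- order(-scores, names(scores))
  n_sens <- floor(p_sensitive / 100 * n)
  warn <- n_sens == 0L
  if (warn) warning("p_sensitive labels zero cells as predicted_sensitive")
  res <- data.frame(cell_id = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_len(n),
                    label = rep(c("predicted_sensitive", "predicted_resistant"),
                                c(n_sens, n - n_sens)),
                    stringsAsFactors = FALSE)
  structure(res, p_sensitive = p_sensitive, warning_empty = warn,
            class = c("StratificationResult", "data.frame"))
}

#' Predicted-sensitive cell ids of a stratification
#'
#' @param strat a `StratificationResult`.
#' @return Character vector of predicted-sensitive cell ids.
#' @export
predicted_sensitive <- function(strat) {
  strat$cell_id[strat$label == "predicted_sensitive"]
}

#' Write a stratification result as CSV
#'
#' Columns: `cell_id`, `score`, `rank`, `label`, `p_sensitive`.
#'
#' @param strat a `StratificationResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stratification_csv <- function(strat, path) {
  df <- as.data.frame(strat)
  df$p_sensitive <- attr(strat, "p_sensitive")
  data.table::fwrite(df, path)
  invisible(path)
}
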