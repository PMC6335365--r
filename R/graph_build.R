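# Proportional thresholding: connectivity matrix -> undirected binary graph.

#' Binarize a connectivity matrix by proportional thresholding
#'
#' Keeps the top `keep_fraction` of the N(N-1)/2 off-diagonal pairs —
#' exactly `floor(keep_fraction * M)` edges — and sets them to 1, all other
#' pairs to 0. Ranking is by signed weight by default (the largest algebraic
#' values survive); set `rank_by = "absolute"` to rank by magnitude, which
#' is the natural choice for signed estimators when strong anticorrelations
#' should count as connections. Ties are broken deterministically by
#' (weight desc, row asc, column asc).
#'
#' @param cm Symmetric numeric matrix (an [connectivity_matrix()] result or
#'   any N x N symmetric matrix); the diagonal is ignored.
#' @param keep_fraction Fraction of pairs to keep, in (0, 1\]. Default 0.2.
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return A `binary_graph`: N x N symmetric 0/1 matrix with zero diagonal
#'   and attributes `keep_fraction` and `n_edges`.
#' @examples
#' w <- matrix(runif(16), 4, 4); w <- (w + t(w)) / 2
#' proportional_threshold(w, 0.5)
#' @export
proportional_threshold <- function(cm, keep_fraction = 0.2,
                                   rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("`cm` must be a square matrix.", call. = FALSE)
  }
  if (max(abs(cm - t(cm))) > 1e-10) {
    stop("`cm` must be symmetric.", call. = FALSE)
  }
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
    keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be in (0, 1].", call. = FALSE)
  }
  n <- nrow(cm)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  w <- cm[ut]
  if (rank_by == "absolute") w <- abs(w)
  if (diff(range(w)) == 0) {
    warning("All off-diagonal weights are equal; ",
      "proportional threshold falls back to the deterministic tie-break.",
      call. = FALSE
    )
  }
  m_keep <- floor(keep_fraction * length(w))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m_keep)]
  adj <- matrix(0L, n, n, dimnames = dimnames(cm))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(adj,
    class = c("binary_graph", "matrix", "array"),
    keep_fraction = keep_fraction, n_edges = m_keep, rank_by = rank_by
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("<binary_graph> ", nrow(x), " nodes, ", attr(x, "n_edges"),
    " edges (keep_fraction = ", attr(x, "keep_fraction"), ")\n",
    sep = ""
  )
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected", diag = FALSE)
}

#' Export a binary graph as a tab-separated edge list
#'
#' @param g A `binary_graph`.
#' @param path Output path; two ROI-label columns, tab-separated.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  labels <- colnames(g)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(g)))
  e <- which(upper.tri(g) & g == 1, arr.ind = TRUE)
  utils::write.table(
    data.frame(from = labels[e[, 1]], to = labels[e[, 2]]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
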