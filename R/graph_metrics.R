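# Graph-theory metrics on binary undirected graphs: segregation
# (clustering, transitivity), integration (path length, efficiency) and
# centrality (betweenness, eigenvector, participation, within-module
# degree z-score). Standard binary-graph definitions; disconnected graphs
# follow the usual conventions (path length averaged over reachable pairs,
# unreachable pairs contribute 0 efficiency).

#' Per-node clustering coefficient
#'
#' \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with \eqn{t_i} triangles through node
#' i; defined as 0 for nodes of degree < 2.
#'
#' @param g A `binary_graph` (symmetric 0/1 matrix, zero diagonal).
#' @return Named numeric vector, one value in \[0, 1\] per node.
#' @export
clustering_coefficient <- function(g) {
  ig <- as_igraph(g)
  out <- igraph::transitivity(ig, type = "local", isolates = "zero")
  setNames(out, colnames(g))
}

#' Global transitivity
#'
#' Ratio of 3 x triangles to connected triples; 0 when the graph has no
#' connected triple.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in \[0, 1\].
#' @export
graph_transitivity <- function(g) {
  out <- igraph::transitivity(as_igraph(g), type = "global")
  if (is.nan(out)) 0 else out
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable node pairs; unreachable pairs
#' are excluded from the mean. 0 for an edgeless graph.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar \eqn{\ge 1} (0 for edgeless graphs).
#' @export
characteristic_path_length <- function(g) {
  out <- igraph::mean_distance(as_igraph(g), unconnected = TRUE)
  if (is.nan(out) || is.na(out)) 0 else out
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over all ordered node pairs;
#' unreachable pairs contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  if (sum(g) == 0) return(0)
  igraph::global_efficiency(as_igraph(g))
}

#' Per-node local efficiency
#'
#' Global efficiency of the subgraph induced on each node's neighbours;
#' 0 for nodes with fewer than 2 neighbours.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of values in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  n <- ncol(g)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(g[i, ] == 1)
    if (length(nb) >= 2) {
      out[i] <- global_efficiency(g[nb, nb, drop = FALSE])
    }
  }
  setNames(out, colnames(g))
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through
#' each node, normalized by (N-1)(N-2)/2.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of nonnegative values.
#' @export
betweenness_centrality <- function(g) {
  # with < 3 nodes there are no intermediate pairs; normalization would
  # divide by zero
  normalize <- ncol(g) > 2
  out <- igraph::betweenness(as_igraph(g), directed = FALSE,
                             normalized = normalize)
  setNames(as.numeric(out), colnames(g))
}

#' Eigenvector centrality on the largest component
#'
#' Leading-eigenvector entries of the adjacency matrix of the largest
#' connected component, max-normalized to 1; nodes outside that component
#' score 0. An edgeless graph scores 0 everywhere.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector in \[0, 1\].
#' @export
eigenvector_centrality <- function(g) {
  n <- ncol(g)
  out <- setNames(numeric(n), colnames(g))
  if (sum(g) == 0) return(out)
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(ig, main)
  ec <- as.numeric(igraph::eigen_centrality(sub)$vector)
  ec <- pmax(ec, 0)
  if (max(ec) > 0) ec <- ec / max(ec)
  out[main] <- ec
  out
}

#' Detect network modules (Louvain)
#'
#' Greedy modularity-maximising (Louvain) community detection, made
#' deterministic by a fixed RNG seed.
#'
#' @inheritParams clustering_coefficient
#' @param seed Integer RNG seed; identical seed + graph give an identical
#'   partition.
#' @return Integer vector of module assignments (1-based), named by node,
#'   with attribute `modularity` holding Q of the returned partition.
#' @export
detect_modules <- function(g, seed = 1L) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0) {
    out <- setNames(seq_len(ncol(g)), colnames(g))
    attr(out, "modularity") <- 0
    return(out)
  }
  cl <- withr::with_seed(seed, igraph::cluster_louvain(ig))
  out <- setNames(as.integer(igraph::membership(cl)), colnames(g))
  attr(out, "modularity") <- igraph::modularity(ig, igraph::membership(cl))
  out
}

#' Modularity of a partition
#'
#' Newman-Girvan modularity Q of a node-to-module assignment; 0 for an
#' edgeless graph.
#'
#' @inheritParams clustering_coefficient
#' @param membership Integer module assignment, one entry per node.
#' @return Scalar in \[-0.5, 1\].
#' @export
graph_modularity <- function(g, membership) {
  if (sum(g) == 0) return(0)
  igraph::modularity(as_igraph(g), membership)
}

#' Participation coefficient
#'
#' \eqn{P_i = 1 - \sum_m (k_{im}/k_i)^2}: how evenly node i's edges spread
#' over modules. 0 for isolated nodes and for nodes whose edges all stay in
#' one module.
#'
#' @inheritParams graph_modularity
#' @return Named numeric vector in \[0, 1\].
#' @export
participation_coefficient <- function(g, membership) {
  n <- ncol(g)
  k <- rowSums(g)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] == 0) next
    kim <- tapply(g[i, ], membership, sum)
    out[i] <- 1 - sum((kim / k[i])^2)
  }
  setNames(out, colnames(g))
}

#' Within-module degree z-score
#'
#' Standardizes each node's within-module degree against the mean and SD of
#' within-module degrees in its own module; 0 where the module SD is 0
#' (including singleton modules).
#'
#' @inheritParams graph_modularity
#' @return Named numeric vector of finite values.
#' @export
within_module_zscore <- function(g, membership) {
  n <- ncol(g)
  k_within <- numeric(n)
  for (i in seq_len(n)) {
    k_within[i] <- sum(g[i, membership == membership[i]])
  }
  out <- numeric(n)
  for (m in unique(membership)) {
    idx <- membership == m
    mu <- mean(k_within[idx])
    s <- sd(k_within[idx])
    out[idx] <- if (is.na(s) || s == 0) 0 else (k_within[idx] - mu) / s
  }
  setNames(out, colnames(g))
}

#' All nodal metrics of a binary graph
#'
#' Computes the seven per-node metrics used as features: degree, clustering
#' coefficient, local efficiency, betweenness centrality, eigenvector
#' centrality, participation coefficient and within-module degree z-score.
#'
#' @inheritParams clustering_coefficient
#' @param membership Module assignment; `NULL` (default) runs
#'   [detect_modules()] with `seed`.
#' @param seed Seed forwarded to [detect_modules()] when `membership` is
#'   `NULL`.
#' @return Tibble with one row per node: `roi` plus the seven metric
#'   columns.
#' @export
nodal_metrics <- function(g, membership = NULL, seed = 1L) {
  if (is.null(membership)) membership <- detect_modules(g, seed = seed)
  labels <- colnames(g)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(g)))
  tibble::tibble(
    roi = labels,
    degree = as.numeric(rowSums(g)),
    clustering = as.numeric(clustering_coefficient(g)),
    local_efficiency = as.numeric(local_efficiency(g)),
    betweenness = as.numeric(betweenness_centrality(g)),
    eigenvector = as.numeric(eigenvector_centrality(g)),
    participation = as.numeric(participation_coefficient(g, membership)),
    within_module_z = as.numeric(within_module_zscore(g, membership))
  )
}

#' All global metrics of a binary graph
#'
#' The five whole-graph metrics used as features: transitivity,
#' characteristic path length, global efficiency, mean clustering
#' coefficient and modularity Q of the detected (or given) partition.
#'
#' @inheritParams nodal_metrics
#' @return One-row tibble with columns `transitivity`, `char_path_length`,
#'   `global_efficiency`, `mean_clustering`, `modularity`.
#' @export
global_metrics <- function(g, membership = NULL, seed = 1L) {
  if (is.null(membership)) membership <- detect_modules(g, seed = seed)
  tibble::tibble(
    transitivity = graph_transitivity(g),
    char_path_length = characteristic_path_length(g),
    global_efficiency = global_efficiency(g),
    mean_clustering = mean(clustering_coefficient(g)),
    modularity = graph_modularity(g, membership)
  )
}
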