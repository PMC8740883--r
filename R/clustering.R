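#' Build a shared-nearest-neighbor (SNN) graph over cells
#'
#' Finds each cell's `k` nearest neighbors (Euclidean distance in PC space,
#' the cell itself included in its own neighbor set), then connects cell
#' pairs with edge weight equal to the Jaccard similarity of their neighbor
#' sets. Edges with weight below `prune` are removed (1/15, the convention
#' of the Seurat ecosystem).
#'
#' @param embeddings Numeric matrix, cells x PCs.
#' @param k Neighborhood size (default 30). Must be < number of cells.
#' @param prune Minimum Jaccard weight retained.
#' @return An undirected weighted [igraph::graph] with one vertex per cell.
#' @export
build_snn_graph <- function(embeddings, k = 30, prune = 1 / 15) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (k >= n) abort(sprintf("k = %d must be smaller than the number of cells (%d).", k, n))
  nn <- knn_euclidean(embeddings, as.integer(k))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)            # |N(i) & N(j)|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j                  # strict upper triangle
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])  # Jaccard s/(2k-s): union = 2k - shared
  ok <- w >= prune
  g <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[ok]
  igraph::V(g)$name <- rownames(embeddings) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection on an SNN graph
#'
#' Thin wrapper over [igraph::cluster_louvain()] exposing the resolution
#' parameter; higher resolutions generally yield more, smaller communities.
#' Deterministic for a fixed R RNG state (set a seed before calling).
#'
#' @param graph Weighted undirected graph from [build_snn_graph()].
#' @param resolution Positive resolution parameter (default 1.2).
#' @return Character vector of cluster labels ("0", "1", ... by decreasing
#'   size), one per vertex, named by vertex.
#' @export
louvain_cluster <- function(graph, resolution = 1.2) {
  stopifnot(resolution > 0)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  m <- igraph::membership(comm)
  # relabel by decreasing community size for stable, readable labels
  sizes <- sort(table(m), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- as.character(relab[as.character(m)])
  names(out) <- igraph::V(graph)$name
  out
}

#' Re-cluster a simulated dataset
#'
#' Convenience wrapper: SNN graph (k nearest neighbors, Jaccard weights)
#' followed by Louvain community detection, attaching the labels as a
#' `new_cluster` column of the dataset's metadata.
#'
#' @param dataset A `sim_data` object.
#' @param k SNN neighborhood size (default 30).
#' @param resolution Louvain resolution; defaults to the design's value.
#' @return The dataset with `meta$new_cluster` filled in.
#' @export
cluster_cells <- function(dataset, k = 30, resolution = NULL) {
  stopifnot(inherits(dataset, "sim_data"))
  resolution <- resolution %||% dataset$design$resolution %||% 1.2
  g <- build_snn_graph(dataset$embeddings, k = k)
  labels <- louvain_cluster(g, resolution = resolution)
  dataset$meta$new_cluster <- unname(labels[dataset$meta$cell])
  dataset
}
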