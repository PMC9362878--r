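#' Exact k-nearest-neighbour graph from an embedding
#'
#' Neighbours are found by exact Euclidean distance in the supplied embedding
#' (typically a PCA subspace); no approximate search is used. Self is
#' excluded. Distance ties are broken deterministically by ascending cell
#' index.
#'
#' @param emb Cells x components numeric matrix with cell ids as rownames.
#' @param k Number of neighbours per cell; must satisfy `k < nrow(emb)`.
#' @return An object of class `neighbor_graph`: list with `knn` (cells x k
#'   integer matrix of neighbour row indices), `cell_ids`, `k`, and `snn`
#'   (`NULL` until [knn_to_snn()] is applied).
#' @export
build_knn <- function(emb, k) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  if (is.null(rownames(emb))) rownames(emb) <- as.character(seq_len(n))
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    # order() is stable on the secondary index, giving deterministic ties
    idx[i, ] <- order(d[i, ], seq_len(n))[seq_len(k)]
  }
  structure(
    list(knn = idx, cell_ids = rownames(emb), k = k, snn = NULL),
    class = "neighbor_graph"
  )
}

#' Shared-nearest-neighbour (SNN) weights from a kNN graph
#'
#' Edge weight between two cells is the Jaccard overlap of their
#' k-neighbour sets, `|N(u) n N(v)| / |N(u) u N(v)|`, a symmetric value in
#' \[0, 1\]. Edges with weight below `prune` are removed.
#'
#' @param g A `neighbor_graph` from [build_knn()].
#' @param prune Pruning threshold in \[0, 1\]; default 1/15.
#' @return The graph with `snn` set to a symmetric sparse `dgCMatrix` of
#'   Jaccard weights (zero diagonal).
#' @export
knn_to_snn <- function(g, prune = 1 / 15) {
  stopifnot(inherits(g, "neighbor_graph"))
  n <- nrow(g$knn)
  k <- g$k
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(g$knn), x = 1,
    dims = c(n, n)
  )
  inter <- Matrix::tcrossprod(adj)              # |N(u) n N(v)|
  inter <- methods::as(inter, "generalMatrix")
  jac <- inter
  jac@x <- jac@x / (2 * k - jac@x)              # |union| = 2k - |intersection|
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  if (prune > 0) {
    jac@x[jac@x < prune] <- 0
    jac <- Matrix::drop0(jac)
  }
  dimnames(jac) <- list(g$cell_ids, g$cell_ids)
  g$snn <- methods::as(jac, "CsparseMatrix")
  g$prune <- prune
  g
}

#' Multi-resolution community detection over an SNN graph
#'
#' Runs modularity-based community detection (Louvain, via
#' [igraph::cluster_louvain()]) once per resolution value on the same SNN
#' graph, with the random seed re-fixed before each run so the result is
#' reproducible. Labels are relabelled by descending cluster size per column
#' (label 0 = largest), matching the convention of the cluster-flow graph.
#' Disconnected graphs are allowed; components are clustered separately by
#' the optimiser.
#'
#' @param g A `neighbor_graph` with SNN weights ([knn_to_snn()]).
#' @param resolutions Strictly increasing numeric grid of resolution values.
#' @param seed Integer seed fixed before every community-detection run.
#' @return A [cell_assignments] matrix (cells x resolutions, size-ordered
#'   labels).
#' @export
cluster_grid <- function(g, resolutions, seed = 1L) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (is.null(g$snn)) stop("run knn_to_snn() before cluster_grid()")
  resolutions <- as.numeric(resolutions)
  if (length(resolutions) < 1L) stop("resolution grid must be non-empty")
  if (is.unsorted(resolutions, strictly = TRUE)) {
    stop("resolutions must be strictly increasing")
  }
  ig <- igraph::graph_from_adjacency_matrix(g$snn, mode = "undirected",
                                            weighted = TRUE)
  lab <- matrix(0L, length(g$cell_ids), length(resolutions))
  for (j in seq_along(resolutions)) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(ig, resolution = resolutions[j])
    lab[, j] <- as.integer(igraph::membership(cl)) - 1L
  }
  relabel_by_size(cell_assignments(g$cell_ids, lab, resolutions))
}
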