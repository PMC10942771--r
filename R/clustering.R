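#' Batch-balanced k-nearest-neighbor graph
#'
#' For every cell, finds its `k_per_batch` nearest neighbors (Euclidean, in
#' the embedding) within each batch separately, so that no batch dominates a
#' cell's neighborhood. The union of directed neighbor relations is
#' symmetrized and weighted by a shared-neighbor connectivity in (0, 1]:
#' `w_ij = (s_ij + 1) / (|N_i| + |N_j| - s_ij + 1)` where `s_ij` counts
#' shared neighbors. A batch with at most `k_per_batch` members contributes
#' all of its cells, with a warning.
#'
#' @param embedding cells x components matrix with cell rownames.
#' @param batch per-cell batch labels.
#' @param k_per_batch neighbors per batch (default 3).
#' @return list of class `neighbor_graph`: `adjacency` (symmetric weighted
#'   sparse matrix, zero diagonal), `neighbors` (directed binary adjacency),
#'   `batch`, `k_per_batch`, `embedding`.
#' @export
batch_balanced_knn <- function(embedding, batch, k_per_batch = 3L) {
  n <- nrow(embedding)
  stopifnot(length(batch) == n, k_per_batch >= 1L)
  if (is.null(rownames(embedding))) rownames(embedding) <- as.character(seq_len(n))
  batch <- as.character(batch)

  ii <- integer(0); jj <- integer(0)
  for (b in unique(batch)) {
    ref_idx <- which(batch == b)
    nb <- length(ref_idx)
    if (nb <= k_per_batch) {
      warning("batch '", b, "' has <= k_per_batch cells; using all of them")
      for (i in seq_len(n)) {
        nbrs <- setdiff(ref_idx, i)
        ii <- c(ii, rep(i, length(nbrs))); jj <- c(jj, nbrs)
      }
      next
    }
    k_query <- k_per_batch + 1L  # the self hit is dropped for in-batch cells
    res <- BiocNeighbors::queryKNN(embedding[ref_idx, , drop = FALSE],
                                   embedding, k = min(k_query, nb))
    for (i in seq_len(n)) {
      nbrs <- ref_idx[res$index[i, ]]
      nbrs <- nbrs[nbrs != i][seq_len(min(k_per_batch, sum(nbrs != i)))]
      ii <- c(ii, rep(i, length(nbrs))); jj <- c(jj, nbrs)
    }
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n),
                            dimnames = list(rownames(embedding),
                                            rownames(embedding)))
  A@x[] <- 1  # collapse duplicates to binary
  S <- Matrix::tcrossprod(A)          # shared-neighbor counts
  deg <- Matrix::rowSums(A)
  E <- methods::as(((A + Matrix::t(A)) > 0) * 1, "CsparseMatrix")
  trip <- Matrix::summary(E)
  s <- S[cbind(trip$i, trip$j)]
  w <- (s + 1) / (deg[trip$i] + deg[trip$j] - s + 1)
  W <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = w, dims = dim(E),
                            dimnames = dimnames(A))
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)

  structure(
    list(adjacency = W, neighbors = A, batch = batch,
         k_per_batch = k_per_batch, embedding = embedding),
    class = "neighbor_graph"
  )
}

.as_igraph <- function(graph) {
  W <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

#' Leiden community detection
#'
#' Runs Leiden on the weighted neighbor graph with the RB-configuration
#' quality function (modularity with a resolution parameter). Cluster labels
#' are "0", "1", ... ordered by decreasing cluster size. Deterministic given
#' `seed`.
#'
#' @param graph a [batch_balanced_knn()] result, a symmetric weighted
#'   adjacency matrix, or an igraph.
#' @param resolution resolution parameter (default 1.3).
#' @param seed RNG seed.
#' @param n_iterations Leiden refinement iterations (default 10).
#' @return named character vector of per-cell labels with attributes
#'   `resolution` and `seed`.
#' @export
leiden_cluster <- function(graph, resolution = 1.3, seed = 0L,
                           n_iterations = 10L) {
  g <- if (inherits(graph, "igraph")) graph else .as_igraph(graph)
  if (igraph::vcount(g) == 0) stop("empty graph")
  comm <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    weights = igraph::E(g)$weight,
    resolution = resolution, n_iterations = n_iterations
  ))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- igraph::V(g)$name
  attr(labels, "resolution") <- resolution
  attr(labels, "seed") <- seed
  labels
}

#' Restricted subclustering
#'
#' Reruns Leiden independently on the subgraph induced by each target
#' cluster; the resulting labels extend the parent label ("5" becomes "5.0",
#' "5.1", ... ordered by subcluster size). Cells outside the targets keep
#' their labels unchanged.
#'
#' @param labels per-cell labels (named).
#' @param graph the neighbor graph the labels were computed on.
#' @param target_labels clusters to subcluster.
#' @param resolution Leiden resolution for the rerun (default 0.37).
#' @param seed RNG seed.
#' @return updated label vector.
#' @export
subcluster <- function(labels, graph, target_labels, resolution = 0.37,
                       seed = 0L) {
  if (length(target_labels) == 0) return(labels)
  missing_t <- setdiff(target_labels, unique(labels))
  if (length(missing_t)) stop("unknown target cluster(s): ",
                              paste(missing_t, collapse = ", "))
  W <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  out <- labels
  for (t in target_labels) {
    cells <- names(labels)[labels == t]
    sub <- leiden_cluster(W[cells, cells, drop = FALSE],
                          resolution = resolution, seed = seed)
    out[cells] <- paste0(t, ".", sub)
  }
  attributes(out) <- attributes(labels)
  out
}

#' Split a cluster on a marker gene
#'
#' Within one cluster, cells expressing `gene` above `tau` (log-normalized)
#' become "<cluster>.1" and the rest "<cluster>.0".
#'
#' @param labels per-cell labels (named by cell).
#' @param lognorm genes x cells log-normalized matrix.
#' @param cluster cluster label to split.
#' @param gene marker gene id.
#' @param tau expression threshold (default 0.5).
#' @return updated label vector.
#' @export
split_by_marker <- function(labels, lognorm, cluster, gene, tau = 0.5) {
  if (!cluster %in% labels) stop("unknown cluster: ", cluster)
  if (!gene %in% rownames(lognorm)) stop("gene not present: ", gene)
  cells <- names(labels)[labels == cluster]
  pos <- lognorm[gene, cells] > tau
  if (all(pos) || !any(pos)) {
    message("cluster ", cluster, ": marker split left one side empty")
  }
  out <- labels
  out[cells] <- paste0(cluster, ifelse(pos, ".1", ".0"))
  attributes(out) <- attributes(labels)
  out
}
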