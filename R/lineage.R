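#' Cluster-graph lineage reconstruction with balanced subsampling
#'
#' Abstracts the cell-level neighbor graph to a cluster graph whose edge
#' weights estimate the confidence that two clusters are developmentally
#' connected. Clusters smaller than `min_cluster_size` are removed. With
#' `balance = TRUE` every remaining cluster is subsampled without replacement
#' to the size of the smallest remaining cluster and the neighbor graph is
#' rebuilt on the subsample with the same parameters, which prevents large
#' clusters from dominating the edge statistics. The connectivity of clusters
#' i and j is `min(1, e_ij / E[e_ij])` where `e_ij` is the observed number of
#' inter-cluster edges and `E[e_ij] = D_i D_j / (2m)` is its expectation
#' under the degree-sum (configuration-model) null with `m` total edges.
#'
#' @param graph a [batch_balanced_knn()] result (required when
#'   `balance = TRUE`, since the graph is rebuilt from the stored embedding).
#' @param labels named per-cell cluster labels.
#' @param balance subsample clusters to equal size (default TRUE).
#' @param min_cluster_size clusters below this size are removed (default 50).
#' @param seed RNG seed for the subsample.
#' @return list of class `cluster_graph`: `nodes` (label, size),
#'   `edges` (from, to, connectivity in [0, 1]), `balanced`, `seed`,
#'   `cells_used`.
#' @export
paga_graph <- function(graph, labels, balance = TRUE, min_cluster_size = 50L,
                       seed = 0L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  cells <- rownames(graph$adjacency)
  labels <- labels[cells]
  sizes <- table(labels)
  keep_clusters <- names(sizes)[sizes >= min_cluster_size]
  if (length(keep_clusters) < 2) {
    stop("fewer than 2 clusters survive the ", min_cluster_size, "-cell filter")
  }
  keep_cells <- cells[labels %in% keep_clusters]

  if (balance) {
    target <- min(sizes[keep_clusters])
    keep_cells <- with_seed(seed, unlist(lapply(sort(keep_clusters), function(cl) {
      cl_cells <- cells[labels == cl]
      if (length(cl_cells) > target) sample(cl_cells, target) else cl_cells
    }), use.names = FALSE))
    sub <- batch_balanced_knn(
      graph$embedding[keep_cells, , drop = FALSE],
      graph$batch[match(keep_cells, cells)],
      k_per_batch = graph$k_per_batch
    )
    W <- sub$adjacency
  } else {
    W <- graph$adjacency[keep_cells, keep_cells]
  }

  lab <- labels[keep_cells]
  B <- (W > 0) * 1                              # binary undirected support
  deg <- Matrix::rowSums(B)
  m <- sum(deg) / 2
  K <- length(keep_clusters)
  ind <- Matrix::sparseMatrix(
    i = seq_along(lab), j = match(lab, keep_clusters), x = 1,
    dims = c(length(lab), K)
  )
  Ecount <- as.matrix(Matrix::t(ind) %*% B %*% ind)  # 2x off-diag edge counts? no:
  # Ecount[i, j] for i != j is exactly e_ij (each undirected edge counted once
  # per ordered pair); diagonal double-counts within-cluster edges.
  D <- as.numeric(Matrix::t(ind) %*% deg)

  edges <- list()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      e_obs <- Ecount[i, j]
      expected <- D[i] * D[j] / (2 * m)
      conn <- if (expected == 0) 0 else min(1, e_obs / expected)
      edges[[length(edges) + 1L]] <- data.frame(
        from = keep_clusters[i], to = keep_clusters[j],
        connectivity = conn, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      nodes = data.frame(label = keep_clusters,
                         size = as.integer(table(lab)[keep_clusters]),
                         stringsAsFactors = FALSE),
      edges = do.call(rbind, edges),
      balanced = balance, seed = seed, cells_used = keep_cells
    ),
    class = "cluster_graph"
  )
}

#' Transcriptome correlation ordering of clusters
#'
#' Computes per-cluster mean log-normalized expression, the pairwise Spearman
#' correlation of those mean transcriptomes, and a Ward hierarchical
#' clustering on the correlation distance `1 - rho`; the dendrogram's leaf
#' order (standard smaller-index-left tie rule) orders the clusters.
#'
#' @param lognorm genes x cells log-normalized matrix.
#' @param labels named per-cell cluster labels.
#' @return list with `correlation` (clusters x clusters Spearman rho),
#'   `order` (cluster labels in leaf order) and `hclust`.
#' @export
correlation_order <- function(lognorm, labels) {
  labels <- labels[colnames(lognorm)]
  if (anyNA(labels)) stop("cluster with 0 cells or unlabeled cells present")
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least 2 clusters")
  ind <- Matrix::sparseMatrix(i = seq_along(labels), j = match(labels, lev),
                              x = 1, dims = c(length(labels), length(lev)))
  sizes <- Matrix::colSums(ind)
  means <- as.matrix(lognorm %*% ind) %*% diag(1 / sizes, length(lev))
  colnames(means) <- lev
  rho <- stats::cor(means, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "ward.D2")
  list(correlation = rho, order = lev[hc$order], hclust = hc)
}

#' Cell-cycle phase scoring
#'
#' Scores each cell for the S and G2M programs as the mean expression of the
#' program genes minus the mean expression of a control set: for every
#' program gene, `n_ctrl` control genes are drawn from the same
#' average-expression bin (`n_bins` equal-size bins over all genes), and the
#' controls are pooled (deduplicated). Phase is S when the S score exceeds
#' both the G2M score and zero; G2M when the G2M score is at least the S
#' score and positive; G1 otherwise.
#'
#' @param lognorm genes x cells log-normalized matrix.
#' @param s_genes,g2m_genes program gene sets.
#' @param n_bins expression bins (default 25).
#' @param n_ctrl control genes per program gene (default 50).
#' @param seed RNG seed for the control draw.
#' @return data.frame with `cell`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_phase <- function(lognorm, s_genes, g2m_genes, n_bins = 25L,
                             n_ctrl = 50L, seed = 0L) {
  genes <- rownames(lognorm)
  s_genes <- intersect(s_genes, genes)
  g2m_genes <- intersect(g2m_genes, genes)
  if (length(s_genes) == 0 || length(g2m_genes) == 0) {
    stop("gene set empty after intersection with the matrix genes")
  }
  gmeans <- Matrix::rowMeans(lognorm)
  bin <- ceiling(rank(gmeans, ties.method = "first") / (length(genes) / n_bins))

  score_set <- function(set, seed_offset) {
    ctrl <- with_seed(seed + seed_offset, unique(unlist(lapply(set, function(g) {
      pool <- genes[bin == bin[match(g, genes)]]
      sample(pool, min(n_ctrl, length(pool)))
    }))))
    Matrix::colMeans(lognorm[set, , drop = FALSE]) -
      Matrix::colMeans(lognorm[ctrl, , drop = FALSE])
  }
  s_score <- score_set(s_genes, 0L)
  g2m_score <- score_set(g2m_genes, 1L)

  phase <- ifelse(s_score > g2m_score & s_score > 0, "S",
                  ifelse(g2m_score >= s_score & g2m_score > 0, "G2M", "G1"))
  data.frame(cell = colnames(lognorm), s_score = unname(s_score),
             g2m_score = unname(g2m_score), phase = unname(phase),
             stringsAsFactors = FALSE)
}
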