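test_that("ICA recovers independent Laplace sources up to sign and permutation", {
  set.seed(41)
  n <- 5000
  S_true <- cbind(rexp(n) * sample(c(-1, 1), n, TRUE),
                  rexp(n) * sample(c(-1, 1), n, TRUE))
  A_mix <- matrix(rnorm(4), 2, 2)
  X <- S_true %*% t(A_mix)                       # observations x 2 mixtures
  lognorm <- t(X)                                # "genes" x "cells"
  rownames(lognorm) <- c("m1", "m2")
  colnames(lognorm) <- sprintf("c%04d", 1:n)
  emb <- ica_embed(lognorm, n_components = 2, seed = 1)
  cors <- abs(stats::cor(emb, S_true))
  # best assignment: each true source matched by some component at |r|>=0.95
  expect_true(all(apply(cors, 2, max) >= 0.95))
})

test_that("rank-2 data is reconstructed exactly with 2 components", {
  set.seed(42)
  U <- matrix(rnorm(200 * 2), 200, 2)
  V <- matrix(rnorm(50 * 2), 50, 2)
  X <- U %*% t(V)                                # cells x genes, rank 2
  lognorm <- t(X)
  dimnames(lognorm) <- list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200))
  emb <- ica_embed(lognorm, n_components = 2, seed = 1)
  recon <- emb %*% t(attr(emb, "gene_loadings"))
  centered <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("ICA embedding is deterministic and sign-fixed", {
  cfg <- small_sim_config(seed = 43)
  sce <- simulate_lineage(cfg)
  ln <- normalize_counts(assay(sce))
  gk <- gene_filter(assay(sce), 50)
  e1 <- ica_embed(ln[gk, ], n_components = 10, seed = 9)
  e2 <- ica_embed(ln[gk, ], n_components = 10, seed = 9)
  expect_identical(e1, e2)
  A <- attr(e1, "gene_loadings")
  for (j in seq_len(ncol(A))) {
    expect_gt(A[which.max(abs(A[, j])), j], 0)
  }
  expect_equal(attr(e1, "vafs"), sort(attr(e1, "vafs"), decreasing = TRUE))
})

test_that("single-batch balanced kNN equals plain kNN (brute-force oracle)", {
  set.seed(44)
  emb <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(sprintf("c%02d", 1:60), NULL))
  g <- batch_balanced_knn(emb, rep("b1", 60), k_per_batch = 3)
  d <- as.matrix(dist(emb))
  for (i in 1:60) {
    brute <- order(d[i, ])[2:4]  # self first, then 3 nearest
    expect_setequal(which(g$neighbors[i, ] > 0), brute)
  }
  # symmetry and zero diagonal
  expect_true(Matrix::isSymmetric(g$adjacency))
  expect_true(all(Matrix::diag(g$adjacency) == 0))
  expect_true(all(g$adjacency@x > 0 & g$adjacency@x <= 1))
})

test_that("shifted-copy batches contribute k neighbors each and bridge clusters", {
  set.seed(45)
  base <- rbind(matrix(rnorm(40 * 2), 40, 2),
                cbind(rnorm(40, mean = 30), rnorm(40)))
  emb <- rbind(base, sweep(base, 2, c(0, 5), `+`))  # batch shift orthogonal
  # to the cluster axis, so corresponding clusters stay nearest across batches
  rownames(emb) <- sprintf("c%03d", 1:160)
  batch <- rep(c("b1", "b2"), each = 80)
  g <- batch_balanced_knn(emb, batch, k_per_batch = 3)
  per_batch <- sapply(1:160, function(i) {
    nb <- which(g$neighbors[i, ] > 0)
    c(sum(batch[nb] == "b1"), sum(batch[nb] == "b2"))
  })
  expect_true(all(per_batch == 3))
  # cross-batch edges connect corresponding clusters: a cell in cluster 1 of
  # b1 neighbors only cluster-1 cells of b2
  cl <- rep(rep(c(1, 2), each = 40), 2)
  for (i in c(1, 41, 81, 121)) {
    nb <- which(g$neighbors[i, ] > 0)
    expect_true(all(cl[nb] == cl[i]))
  }

  # k_per_batch = 1 with 3 batches: at most 3 directed neighbors
  batch3 <- rep(c("x", "y", "z"), length.out = 160)
  g3 <- batch_balanced_knn(emb, batch3, k_per_batch = 1)
  expect_true(all(Matrix::rowSums(g3$neighbors > 0) <= 3))

  # tiny batch triggers the take-all warning
  expect_warning(
    batch_balanced_knn(emb, c(rep("big", 157), rep("tiny", 3)), k_per_batch = 3),
    "tiny"
  )
})

test_that("Leiden resolves structure and behaves in limits", {
  # two disconnected 50-cliques
  A <- Matrix::bdiag(matrix(1, 50, 50), matrix(1, 50, 50))
  Matrix::diag(A) <- 0
  dimnames(A) <- list(sprintf("c%03d", 1:100), sprintf("c%03d", 1:100))
  lab <- leiden_cluster(A, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:50])), 1)
  expect_equal(length(unique(lab[51:100])), 1)
  # labels ordered by size: both 50 -> "0" and "1"
  expect_setequal(unique(lab), c("0", "1"))

  # resolution -> 0 on a connected graph: a single community
  set.seed(46)
  emb <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(sprintf("c%02d", 1:80), NULL))
  g <- batch_balanced_knn(emb, rep("b", 80), 4)
  lab0 <- leiden_cluster(g, resolution = 1e-6, seed = 1)
  expect_equal(length(unique(lab0)), 1)

  expect_error(leiden_cluster(igraph::make_empty_graph(0)), "empty")
})

test_that("subclustering is restricted, prefixed and leaves non-targets untouched", {
  A <- Matrix::bdiag(matrix(1, 30, 30), matrix(1, 30, 30), matrix(1, 40, 40))
  Matrix::diag(A) <- 0
  cells <- sprintf("c%03d", 1:100)
  dimnames(A) <- list(cells, cells)
  labels <- stats::setNames(c(rep("T", 60), rep("other", 40)), cells)

  expect_identical(subcluster(labels, A, character(0)), labels)
  expect_error(subcluster(labels, A, "nope"), "unknown target")

  out <- subcluster(labels, A, "T", resolution = 1, seed = 1)
  expect_setequal(unique(out[1:60]), c("T.0", "T.1"))
  expect_identical(out[61:100], labels[61:100])
  expect_equal(length(unique(out[1:30])), 1)
  expect_equal(length(unique(out[31:60])), 1)
})

test_that("marker splitting thresholds cells exactly", {
  cells <- sprintf("c%02d", 1:50)
  vals <- c(runif(20, 0.6, 2), rep(0, 30))
  m <- Matrix::Matrix(matrix(vals, 1, dimnames = list("Pax8", cells)), sparse = TRUE)
  labels <- stats::setNames(rep("5", 50), cells)
  out <- split_by_marker(labels, m, "5", "Pax8")
  expect_equal(sum(out == "5.1"), 20)
  expect_equal(sum(out == "5.0"), 30)
  expect_equal(unname(out[1:20]), rep("5.1", 20))

  expect_message(all0 <- split_by_marker(labels, m, "5", "Pax8", tau = Inf),
                 "empty")
  expect_true(all(all0 == "5.0"))
  expect_error(split_by_marker(labels, m, "9", "Pax8"), "unknown cluster")
  expect_error(split_by_marker(labels, m, "5", "Nope"), "not present")
})
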