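make_graph_from_embedding <- function(emb, k = 4) {
  rownames(emb) <- sprintf("c%04d", seq_len(nrow(emb)))
  batch_balanced_knn(emb, rep("b1", nrow(emb)), k_per_batch = k)
}

test_that("disconnected populations get zero connectivity", {
  set.seed(51)
  emb <- rbind(matrix(rnorm(120 * 2), 120, 2),
               matrix(rnorm(120 * 2, mean = 1000), 120, 2))
  g <- make_graph_from_embedding(emb)
  labels <- stats::setNames(rep(c("A", "B"), each = 120), rownames(g$adjacency))
  cg <- paga_graph(g, labels, balance = TRUE, min_cluster_size = 50, seed = 1)
  expect_equal(cg$edges$connectivity, 0)
})

test_that("a three-population chain has strong adjacent and weak distal links", {
  set.seed(52)
  emb <- rbind(matrix(rnorm(150 * 2, 0, 0.8), 150, 2),
               matrix(rnorm(150 * 2, 3, 0.8), 150, 2),
               matrix(rnorm(150 * 2, 6, 0.8), 150, 2))
  g <- make_graph_from_embedding(emb)
  labels <- stats::setNames(rep(c("A", "B", "C"), each = 150),
                            rownames(g$adjacency))
  cg <- paga_graph(g, labels, seed = 2)
  conn <- function(a, b) {
    e <- cg$edges
    e$connectivity[(e$from == a & e$to == b) | (e$from == b & e$to == a)]
  }
  expect_gte(conn("A", "B"), 5 * max(conn("A", "C"), 1e-6))
  expect_gte(conn("B", "C"), 5 * max(conn("A", "C"), 1e-6))
  # symmetry by construction: each unordered pair appears once
  expect_equal(nrow(cg$edges), 3)
  expect_true(all(cg$edges$connectivity >= 0 & cg$edges$connectivity <= 1))
})

test_that("balancing subsamples every cluster to the smallest surviving size", {
  set.seed(53)
  emb <- rbind(matrix(rnorm(1000 * 2), 1000, 2),
               matrix(rnorm(60 * 2, mean = 8), 60, 2))
  g <- make_graph_from_embedding(emb)
  labels <- stats::setNames(rep(c("big", "small"), c(1000, 60)),
                            rownames(g$adjacency))
  cg <- paga_graph(g, labels, balance = TRUE, min_cluster_size = 50, seed = 3)
  expect_equal(cg$nodes$size, c(60L, 60L))

  # a cluster below the size floor is removed entirely
  labels2 <- labels
  labels2[1:20] <- "tiny"
  cg2 <- paga_graph(g, labels2, min_cluster_size = 50, seed = 3)
  expect_false("tiny" %in% cg2$nodes$label)
  expect_error(paga_graph(g, stats::setNames(rep(c("a", "b"), c(1040, 20)),
                                             rownames(g$adjacency)),
                          min_cluster_size = 50),
               "fewer than 2")
})

test_that("correlation ordering reflects transcriptome similarity", {
  set.seed(54)
  base <- matrix(rpois(100 * 40, 5), 100, 40)
  m <- cbind(base, base)  # cluster B duplicates cluster A cell-for-cell
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("c%03d", 1:80))
  labels <- stats::setNames(rep(c("A", "B"), each = 40), colnames(m))
  res <- correlation_order(Matrix::Matrix(m, sparse = TRUE), labels)
  expect_equal(res$correlation["A", "B"], 1)

  # anti-correlated mean profiles: rho = -1, i.e. distance 2
  up <- matrix(rep(1:50, 10), 50, 10)
  down <- matrix(rep(50:1, 10), 50, 10)
  m2 <- cbind(up, down)
  dimnames(m2) <- list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20))
  labels2 <- stats::setNames(rep(c("up", "down"), each = 10), colnames(m2))
  res2 <- correlation_order(Matrix::Matrix(m2, sparse = TRUE), labels2)
  expect_equal(res2$correlation["up", "down"], -1)

  # invariant to gene and cell order
  pg <- sample(nrow(m)); pc <- sample(ncol(m))
  res3 <- correlation_order(Matrix::Matrix(m[pg, pc], sparse = TRUE), labels)
  expect_equal(res3$correlation, res$correlation)

  expect_error(correlation_order(Matrix::Matrix(m, sparse = TRUE),
                                 labels[1:10]), "0 cells|unlabeled")
})

test_that("late SLCs sit transcriptionally nearer the supporting fates than the surface epithelium", {
  cfg <- small_sim_config(seed = 55)
  sce <- simulate_lineage(cfg)
  cd <- colData(sce)
  ln <- normalize_counts(assay(sce))
  late <- cd$population == "SLC_late" & cd$stage_idx == 4
  keep <- late | cd$population %in% c("Sertoli", "Granulosa", "SE")
  labels <- stats::setNames(ifelse(late[keep], "SLC_late",
                                   cd$population[keep]),
                            colnames(sce)[keep])
  res <- correlation_order(ln[, names(labels)], labels)
  rho <- res$correlation
  expect_gt(rho["SLC_late", "Sertoli"], rho["SLC_late", "SE"])
  expect_gt(rho["SLC_late", "Granulosa"], rho["SLC_late", "SE"])
})

test_that("cell-cycle scores are zero on a constant matrix and deterministic", {
  m <- Matrix::Matrix(matrix(1, 60, 30,
                             dimnames = list(sprintf("g%02d", 1:60),
                                             sprintf("c%02d", 1:30))),
                      sparse = TRUE)
  res <- cell_cycle_phase(m, sprintf("g%02d", 1:5), sprintf("g%02d", 6:10),
                          seed = 1)
  expect_true(all(res$s_score == 0))
  expect_true(all(res$g2m_score == 0))
  expect_true(all(res$phase == "G1"))

  cfg <- small_sim_config(seed = 56)
  sce <- simulate_lineage(cfg)
  ln <- normalize_counts(assay(sce))
  tr <- metadata(sce)$truth
  r1 <- cell_cycle_phase(ln, tr$s_genes, tr$g2m_genes, seed = 7)
  r2 <- cell_cycle_phase(ln, tr$s_genes, tr$g2m_genes, seed = 7)
  expect_identical(r1, r2)

  expect_error(cell_cycle_phase(m, "absent1", sprintf("g%02d", 6:10)),
               "empty")
})

test_that("spiked cycling cells are phased correctly and quiescent SLCs rest in G1", {
  cfg <- small_sim_config(seed = 57)
  sce <- simulate_lineage(cfg)
  cd <- colData(sce)
  ln <- normalize_counts(assay(sce))
  tr <- metadata(sce)$truth
  cc <- cell_cycle_phase(ln, tr$s_genes, tr$g2m_genes, seed = 1)
  # at this reduced size the phase margins are a little looser than at the
  # full simulation scale exercised by the acceptance suite
  expect_gte(mean(cc$phase[cd$phase == "S"] == "S"), 0.85)
  expect_gte(mean(cc$phase[cd$phase == "G2M"] == "G2M"), 0.85)
  slc <- cd$population %in% c("SLC_early", "SLC_late")
  expect_gte(mean(cc$phase[slc] == "G1"), 0.9)
})
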