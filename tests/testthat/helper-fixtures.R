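# Shared fixtures and independent oracle implementations used across tests.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

# Small lineage config: fast enough for unit tests, same structure as the
# defaults.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    n_genes = 800L,
    marker_block_size = 20L,
    n_cells_per_population = c(
      CE = 160L, SE = 120L, preSup = 140L, Sertoli = 100L,
      Granulosa = 100L, SLC_early = 80L, SLC_late = 140L
    ),
    n_ambient_barcodes = 400L,
    ...
  )
}

# Adjusted Rand index (independent implementation, small n).
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Brute-force step-up BH, independent of p.adjust.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force numeric maximization of the two-part hurdle likelihood for one
# gene; returns the summed LR statistic. Independent of the closed forms in
# hurdle_test.
hurdle_lr_bruteforce <- function(va, vb) {
  det_a <- as.numeric(va > 0); det_b <- as.numeric(vb > 0)
  bern_ll <- function(y, p) sum(y * log(p) + (1 - y) * log(1 - p))
  opt_p <- function(y) {
    stats::optimize(function(p) bern_ll(y, p), c(1e-9, 1 - 1e-9),
                    maximum = TRUE, tol = 1e-12)$objective
  }
  ll1 <- opt_p(det_a) + opt_p(det_b)
  ll0 <- opt_p(c(det_a, det_b))
  lr_disc <- 2 * (ll1 - ll0)

  ya <- va[va > 0]; yb <- vb[vb > 0]
  norm_ll <- function(res, n, s2) -n / 2 * log(2 * pi * s2) - sum(res^2) / (2 * s2)
  # alternative: two means, pooled MLE variance
  f_alt <- function(th) {
    s2 <- exp(th[3])
    -(norm_ll(ya - th[1], length(ya), s2) + norm_ll(yb - th[2], length(yb), s2))
  }
  f_null <- function(th) {
    s2 <- exp(th[2])
    -norm_ll(c(ya, yb) - th[1], length(ya) + length(yb), s2)
  }
  o1 <- stats::optim(c(mean(ya), mean(yb), log(stats::var(c(ya, yb)))), f_alt,
                     control = list(reltol = 1e-14, maxit = 10000))
  o0 <- stats::optim(c(mean(c(ya, yb)), log(stats::var(c(ya, yb)))), f_null,
                     control = list(reltol = 1e-14, maxit = 10000))
  lr_cont <- 2 * (o0$value - o1$value)
  lr_disc + lr_cont
}

# Coordinate-descent LASSO (gaussian, intercept, no standardization),
# objective 1/(2n) ||y - b0 - X b||^2 + lambda ||b||_1. Independent oracle
# for train_signature.
cd_lasso <- function(X, y, lambda, tol = 1e-12, max_sweeps = 5000) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  b <- numeric(p); b0 <- mean(y)
  r <- y - b0
  xss <- colSums(X^2) / n
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xss[j] == 0) next
      rho <- sum(X[, j] * r) / n + xss[j] * b[j]
      bj <- sign(rho) * max(0, abs(rho) - lambda) / xss[j]
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    b0_new <- b0 + mean(r)
    r <- r - (b0_new - b0)
    delta <- max(delta, abs(b0_new - b0))
    b0 <- b0_new
    if (delta < tol) break
  }
  list(intercept = b0, beta = b)
}

# Direct lognorm-scale two-group generator for DE power studies: each gene is
# zero with prob 1 - p_det, else positive-truncated normal.
make_hurdle_groups <- function(n_per, n_genes, n_de, mu0 = 1.5, p0 = 0.4,
                               mu_shift = 1.0, p_shift = 0.2, sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  mk <- function(n, p, mu) {
    d <- matrix(stats::rbinom(n_genes * n, 1, p), n_genes, n)
    v <- matrix(pmax(stats::rnorm(n_genes * n, mu, sd), 0.01), n_genes, n)
    d * v
  }
  A <- mk(n_per, p0, mu0)
  B <- mk(n_per, p0, mu0)
  if (n_de > 0) A[seq_len(n_de), ] <- mk(n_per, p0 + p_shift, mu0 + mu_shift)[seq_len(n_de), ]
  X <- cbind(A, B)
  rownames(X) <- sprintf("g%04d", seq_len(n_genes))
  colnames(X) <- c(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  list(
    lognorm = Matrix(X, sparse = TRUE),
    group_a = paste0("a", seq_len(n_per)),
    group_b = paste0("b", seq_len(n_per)),
    de_genes = rownames(X)[seq_len(n_de)]
  )
}

# Planted-signature training data on the log-normalized scale.
make_signature_data <- function(n_per_class = 300, n_sig = 10, n_noise = 500,
                                effect = 1.0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  ng <- n_sig + n_noise
  X <- matrix(pmax(stats::rnorm(ng * n, 1, 0.7), 0), ng, n)
  y <- rep(c(1, 0), each = n_per_class)
  X[seq_len(n_sig), y == 1] <- X[seq_len(n_sig), y == 1] + effect
  dimnames(X) <- list(sprintf("g%04d", seq_len(ng)), sprintf("c%04d", seq_len(n)))
  labels <- stats::setNames(ifelse(y == 1, "target", "rest"), colnames(X))
  list(lognorm = Matrix(X, sparse = TRUE), labels = labels,
       signature = rownames(X)[seq_len(n_sig)])
}
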