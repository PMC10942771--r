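#' ICA embedding of log-normalized expression
#'
#' Embeds cells by independent component analysis: the genes x cells matrix
#' is transposed, gene-centered, whitened through a (partial) SVD, and
#' rotated by fastICA-family estimation (parallel algorithm, logcosh
#' contrast). Components are ordered by the variance they account for,
#' scaled so each component's standard deviation reflects the variance it
#' explains (keeping Euclidean distances in the embedding signal-weighted,
#' as with PCA scores), and sign-fixed so that each component's
#' largest-magnitude gene loading is positive. Deterministic given `seed`.
#'
#' @param lognorm genes x cells log-normalized matrix, typically restricted
#'   to [gene_filter()] genes.
#' @param n_components number of components (default 100).
#' @param seed RNG seed for the SVD initialization.
#' @param max_iter,tol fixed-point iteration controls.
#' @return cells x components matrix of source estimates, with attributes
#'   `gene_loadings` (genes x components mixing matrix, so that the centered
#'   input is approximately `S %*% t(gene_loadings)`), `vafs` (variance
#'   accounted for), and `converged`.
#' @export
ica_embed <- function(lognorm, n_components = 100L, seed = 1L,
                      max_iter = 100L, tol = 1e-6) {
  X <- t(as.matrix(lognorm))                      # cells x genes
  stopifnot(n_components <= min(dim(X)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)

  k <- n_components
  if (k < 0.5 * min(dim(Xc)) && min(dim(Xc)) > 6) {
    sv <- with_seed(seed, irlba::irlba(Xc, nv = k))
  } else {
    sv <- svd(Xc, nu = k, nv = k)
    sv$d <- sv$d[seq_len(k)]
  }
  Z <- sv$u %*% diag(sv$d, k, k)                  # cells x k scores

  fit <- with_seed(seed, ica::icafast(Z, nc = k, center = TRUE,
                                      maxit = max_iter, tol = tol))
  S <- fit$S                                      # cells x k sources
  A <- sv$v %*% fit$M                             # genes x k mixing

  ord <- order(fit$vafs, decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  A <- A[, ord, drop = FALSE]
  vafs <- fit$vafs[ord]

  # variance-weighted sources: scale S by sqrt(vaf), A inversely, so the
  # reconstruction S %*% t(A) is unchanged
  sc <- sqrt(pmax(vafs, .Machine$double.eps))
  S <- S %*% diag(sc, length(sc))
  A <- A %*% diag(1 / sc, length(sc))

  for (j in seq_len(ncol(S))) {
    if (A[which.max(abs(A[, j])), j] < 0) {
      A[, j] <- -A[, j]
      S[, j] <- -S[, j]
    }
  }
  dimnames(S) <- list(colnames(lognorm), paste0("IC", seq_len(ncol(S))))
  dimnames(A) <- list(rownames(lognorm), colnames(S))
  attr(S, "gene_loadings") <- A
  attr(S, "center") <- mu
  attr(S, "vafs") <- vafs
  attr(S, "converged") <- fit$iter < max_iter
  S
}
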