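#' Log-normalize counts with high-expressor exclusion
#'
#' Per cell, counts are divided by the cell's total UMIs after excluding very
#' highly expressed genes (those exceeding `high_frac` of the cell total)
#' from the denominator, multiplied by `scale`, and natural-log transformed
#' as `ln(1 + scale * x / T')`. Excluded genes keep their values -- only the
#' denominator changes. The high-expressor set is determined in a single pass
#' from the full total. With `high_frac = 1` this reduces to classic
#' total-count log-normalization.
#'
#' @param x genes x cells count matrix, or a SingleCellExperiment with a
#'   `counts` assay (in which case a `lognorm` assay is added and the object
#'   returned).
#' @param scale scale factor (default 10000).
#' @param high_frac exclusion fraction in (0, 1] (default 0.05).
#' @return matrix of log-normalized values (or the augmented
#'   SingleCellExperiment).
#' @export
normalize_counts <- function(x, scale = 1e4, high_frac = 0.05) {
  stopifnot(scale > 0, high_frac > 0, high_frac <= 1)
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
    SummarizedExperiment::assay(x, "lognorm") <-
      normalize_counts(m, scale = scale, high_frac = high_frac)
    return(x)
  }
  m <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts; values set to 0")
  }
  col_of <- rep.int(seq_len(ncol(m)), diff(m@p))
  vals <- m@x
  high <- vals > high_frac * totals[col_of]
  excluded <- numeric(ncol(m))
  if (any(high)) {
    ex <- tapply(vals[high], col_of[high], sum)
    excluded[as.integer(names(ex))] <- ex
  }
  denom <- totals - excluded
  denom[denom == 0] <- totals[denom == 0]          # all mass excluded: fall back
  f <- ifelse(totals == 0, 0, scale / denom)
  out <- m
  out@x <- log1p(vals * f[col_of])
  out
}

#' Filter genes by the number of expressing cells
#'
#' Keeps genes with a nonzero value in strictly more than `min_cells` cells.
#'
#' @param x genes x cells matrix (raw or log-normalized) or a
#'   SingleCellExperiment.
#' @param min_cells strict lower bound (default 50).
#' @return character vector of retained gene ids.
#' @export
gene_filter <- function(x, min_cells = 50L) {
  m <- .get_assay(x, "counts")
  n_expr <- Matrix::rowSums(m > 0)
  keep <- n_expr > min_cells
  if (!any(keep)) stop("no genes expressed in more than ", min_cells, " cells")
  rownames(m)[keep]
}

#' Fraction of cells expressing a gene above a threshold
#'
#' @param lognorm genes x cells log-normalized matrix.
#' @param gene gene id.
#' @param cells cell subset (names or indices).
#' @param tau expression threshold on the log-normalized scale (default 0.5).
#' @return fraction in [0, 1].
#' @export
expressing_fraction <- function(lognorm, gene, cells, tau = 0.5) {
  if (length(cells) == 0) stop("empty cell subset")
  mean(lognorm[gene, cells] > tau)
}
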