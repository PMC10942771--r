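#' Specification of a palindromic locus to rescue
#'
#' Defaults describe exon 2 of Sry on chrY, whose palindromic context makes
#' every genuine negative-strand read also report a positive-strand alignment
#' and be discarded as a multimapper by standard counting.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval.
#' @param strand_required strand carrying genuine molecules ("+" or "-").
#' @param nh_max_exclusive reads are kept when NH < this value.
#' @param gene_name gene tag assigned to rescued reads.
#' @param overlap membership rule: `"any"` keeps reads whose aligned span
#'   overlaps the interval; `"start"` requires the leftmost position inside.
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(chrom = "chrY", start = 2653159L, end = 2655636L,
                       strand_required = "-", nh_max_exclusive = 3L,
                       gene_name = "Sry", overlap = c("any", "start")) {
  stopifnot(start <= end, nh_max_exclusive >= 1L,
            strand_required %in% c("+", "-"))
  overlap <- match.arg(overlap)
  structure(
    list(chrom = chrom, start = start, end = end,
         strand_required = strand_required,
         nh_max_exclusive = nh_max_exclusive,
         gene_name = gene_name, overlap = overlap),
    class = "locus_spec"
  )
}

#' Rescue reads from a palindromic locus
#'
#' Keeps exactly the reads on the required strand, with NH below the
#' multimapper cutoff, whose aligned span `[pos, pos + aln_len - 1]` overlaps
#' the locus interval (closed, 1-based), and sets their gene tag. Input order
#' is preserved; the operation is idempotent.
#'
#' @param reads data.frame of read records with columns `chrom`, `pos`,
#'   `aln_len`, `strand`, `NH`, `CB`, `UB`, `GN`.
#' @param locus a [locus_spec()].
#' @return the retained reads with `GN` set to `locus$gene_name`.
#' @export
rescue_reads <- function(reads, locus = locus_spec()) {
  stopifnot(inherits(locus, "locus_spec"))
  if (nrow(reads) == 0) return(reads)
  span_end <- reads$pos + reads$aln_len - 1L
  hit <- if (locus$overlap == "any") {
    reads$pos <= locus$end & span_end >= locus$start
  } else {
    reads$pos >= locus$start & reads$pos <= locus$end
  }
  keep <- reads$chrom == locus$chrom &
    reads$strand == locus$strand_required &
    reads$NH < locus$nh_max_exclusive &
    hit
  out <- reads[keep, , drop = FALSE]
  out$GN <- rep(locus$gene_name, nrow(out))
  rownames(out) <- NULL
  out
}

#' UMI-deduplicated per-cell counts
#'
#' Collapses rescued reads to molecule counts within each (cell barcode,
#' gene) group. `method = "unique"` counts distinct UMIs. `method =
#' "directional"` applies the directional adjacency rule: an edge runs from
#' UMI u to UMI v when their Hamming distance is 1 and reads(u) >=
#' 2*reads(v) - 1; molecules are the clusters grown from the most abundant
#' unvisited UMI (ties broken lexicographically), following directed edges
#' transitively.
#'
#' @param rescued data.frame of reads with `CB`, `UB`, `GN` set.
#' @param method `"directional"` (default) or `"unique"`.
#' @return data.frame with columns `CB`, `gene`, `count`.
#' @export
dedup_count <- function(rescued, method = c("directional", "unique")) {
  method <- match.arg(method)
  if (nrow(rescued) == 0) {
    return(data.frame(CB = character(0), gene = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  if (anyNA(rescued$CB) || anyNA(rescued$UB) || anyNA(rescued$GN)) {
    stop("all reads must have CB, UB and GN set")
  }
  key <- paste(rescued$CB, rescued$GN, sep = "\r")
  groups <- split(rescued$UB, key)
  counts <- vapply(groups, function(umis) {
    if (length(unique(nchar(umis))) > 1) {
      stop("UMIs of unequal length within a (CB, gene) group")
    }
    if (method == "unique") length(unique(umis)) else .directional_count(umis)
  }, integer(1))
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(CB = parts[, 1], gene = parts[, 2],
                    count = as.integer(counts), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$CB, out$gene), , drop = FALSE]
}

.directional_count <- function(umis) {
  tab <- table(umis)
  u <- names(tab)
  n <- as.integer(tab)
  k <- length(u)
  if (k == 1) return(1L)
  # adjacency: i -> j allowed when hamming == 1 and n_i >= 2 n_j - 1
  chars <- strsplit(u, "")
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && n[i] >= 2L * n[j] - 1L &&
          sum(chars[[i]] != chars[[j]]) == 1L) {
        adj[i, j] <- TRUE
      }
    }
  }
  ord <- order(-n, u)
  visited <- rep(FALSE, k)
  clusters <- 0L
  for (root in ord) {
    if (visited[root]) next
    clusters <- clusters + 1L
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nxt <- which(adj[i, ] & !visited)
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  clusters
}

#' Merge rescued locus counts into a count matrix
#'
#' Sets (does not add, unless `add = TRUE`) the rescued gene's counts for the
#' rescued cells; a gene row is created if absent. Counts for barcodes not in
#' the matrix are dropped with a message reporting how many.
#'
#' @param counts genes x cells matrix.
#' @param locus_counts data.frame from [dedup_count()] (columns `CB`,
#'   `gene`, `count`); must concern a single gene.
#' @param gene_name gene row to fill (defaults to the gene in
#'   `locus_counts`).
#' @param add if TRUE, add to any existing value instead of replacing it.
#' @return the updated matrix.
#' @export
merge_counts <- function(counts, locus_counts, gene_name = NULL, add = FALSE) {
  if (nrow(locus_counts) == 0) return(counts)
  if (is.null(gene_name)) {
    gene_name <- unique(locus_counts$gene)
    stopifnot(length(gene_name) == 1)
  }
  present <- locus_counts$CB %in% colnames(counts)
  n_dropped <- sum(!present)
  if (n_dropped > 0) {
    message(n_dropped, " locus count(s) for barcodes absent from the matrix dropped")
  }
  locus_counts <- locus_counts[present, , drop = FALSE]
  if (!gene_name %in% rownames(counts)) {
    new_row <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(1, ncol(counts)),
      dimnames = list(gene_name, colnames(counts))
    )
    counts <- rbind(counts, new_row)
  }
  if (nrow(locus_counts) > 0) {
    old <- if (add) counts[gene_name, locus_counts$CB] else 0
    counts[gene_name, locus_counts$CB] <- old + locus_counts$count
  }
  counts
}
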