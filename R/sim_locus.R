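#' Simulate aligned reads over a palindromic locus
#'
#' Emits read records emulating a palindromic region where every genuine
#' molecule aligns on the required (negative) strand with a small number of
#' reported alignments (NH of 1 or 2), is mirrored by a positive-strand copy,
#' and is accompanied by NH >= 3 multimappers and duplicated UMIs. Molecule
#' UMIs within a cell are drawn at pairwise Hamming distance >= 2, so
#' error-free directional deduplication recovers the molecule count exactly.
#'
#' @param config a [sim_config()]; the locus fields and `seed` are used.
#' @param cells character vector of cell barcodes.
#' @param n_molecules optional named integer vector of molecules per cell
#'   (overrides the Poisson/expression-fraction draw).
#' @return list with `reads`, a data.frame of read records (columns `chrom`,
#'   `pos`, `aln_len`, `strand`, `NH`, `CB`, `UB`, `GN`; `GN` unset), and
#'   `truth`, the named per-cell molecule counts.
#' @export
simulate_locus_reads <- function(config, cells, n_molecules = NULL) {
  stopifnot(inherits(config, "sim_config"), length(cells) > 0)
  with_seed(config$seed, .simulate_locus_impl(config, cells, n_molecules))
}

.rand_umi <- function(k, len) {
  vapply(seq_len(k), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Draw n UMIs with pairwise Hamming distance >= 2.
.distinct_umis <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .rand_umi(1, len)
    if (all(vapply(out, function(u) .hamming(u, cand) >= 2, logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}

.simulate_locus_impl <- function(config, cells, n_molecules) {
  start <- config$locus_interval[1]
  end <- config$locus_interval[2]
  len <- config$read_len
  pos_range <- seq.int(start, max(start, end - len + 1L))

  if (is.null(n_molecules)) {
    expressing <- stats::rbinom(length(cells), 1, config$locus_expr_frac) == 1
    n_molecules <- ifelse(expressing, stats::rpois(length(cells), config$locus_mol_mean), 0L)
    names(n_molecules) <- cells
  } else {
    n_molecules <- n_molecules[cells]
    names(n_molecules) <- cells
  }

  rows <- list()
  add <- function(pos, strand, nh, cb, ub) {
    data.frame(chrom = config$locus_chrom, pos = pos, aln_len = len,
               strand = strand, NH = nh, CB = cb, UB = ub,
               GN = NA_character_, stringsAsFactors = FALSE)
  }

  for (cb in cells) {
    m <- n_molecules[[cb]]
    if (m > 0) {
      umis <- .distinct_umis(m, config$umi_len)
      for (u in umis) {
        pos <- sample(pos_range, 1)
        nh <- sample(1:2, 1)
        rows[[length(rows) + 1L]] <- add(pos, "-", nh, cb, u)      # genuine
        rows[[length(rows) + 1L]] <- add(pos, "+", nh, cb, u)      # mirror
        n_dup <- stats::rgeom(1, prob = 1 - config$locus_dup_rate)
        if (n_dup > 0) {
          for (d in seq_len(n_dup)) {
            rows[[length(rows) + 1L]] <- add(pos, "-", nh, cb, u)  # duplicate
          }
        }
      }
    }
    n_decoy <- config$locus_decoy_per_cell
    if (n_decoy > 0) {
      n_multi <- ceiling(n_decoy / 2)
      for (d in seq_len(n_multi)) {
        rows[[length(rows) + 1L]] <- add(sample(pos_range, 1),
                                         sample(c("+", "-"), 1),
                                         sample(3:6, 1), cb,
                                         .rand_umi(1, config$umi_len))
      }
      for (d in seq_len(n_decoy - n_multi)) {
        rows[[length(rows) + 1L]] <- add(sample(pos_range, 1), "+",
                                         sample(1:2, 1), cb,
                                         .rand_umi(1, config$umi_len))
      }
    }
  }

  reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), aln_len = integer(0),
               strand = character(0), NH = integer(0), CB = character(0),
               UB = character(0), GN = character(0), stringsAsFactors = FALSE)
  list(reads = reads, truth = n_molecules)
}
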