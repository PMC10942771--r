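#' Write a count matrix in 10x-style MTX layout
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` into a directory.
#'
#' @param counts genes x barcodes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tenx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a 10x-style MTX directory
#'
#' @param dir directory holding `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return genes x barcodes sparse matrix.
#' @export
read_tenx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Read aligned read records (tabular, SAM or BAM)
#'
#' Tabular files (`.tsv`) must carry columns `chrom`, `pos`, `aln_len`,
#' `strand`, `NH`, `CB`, `UB` and optionally `GN`. SAM/BAM files are read
#' through Rsamtools/GenomicAlignments with tags NH, CB, UB, GN; the aligned
#' length is the reference width of the alignment.
#'
#' @param path file path.
#' @return data.frame of read records.
#' @export
read_read_records <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(pos = "integer"))
    if (is.null(df$GN)) df$GN <- NA_character_
    return(df)
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("reading SAM/BAM requires Rsamtools and GenomicAlignments")
  }
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(tag = c("NH", "CB", "UB", "GN"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(ga)
  data.frame(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = GenomicAlignments::start(ga),
    aln_len = GenomicAlignments::width(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    NH = as.integer(mc$NH),
    CB = as.character(mc$CB),
    UB = as.character(mc$UB),
    GN = if (is.null(mc$GN)) NA_character_ else as.character(mc$GN),
    stringsAsFactors = FALSE
  )
}

#' Write read records as tabular TSV or SAM text
#'
#' @param reads data.frame of read records.
#' @param path destination; `.sam` produces SAM text with a minimal header,
#'   anything else a TSV.
#' @param seqlen reference length reported in the SAM header.
#' @return `path`, invisibly.
#' @export
write_read_records <- function(reads, path, seqlen = 91744698L) {
  if (tolower(tools::file_ext(path)) == "sam") {
    chroms <- unique(reads$chrom)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", chroms, seqlen))
    body <- sprintf(
      "r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d\tCB:Z:%s\tUB:Z:%s%s",
      seq_len(nrow(reads)),
      ifelse(reads$strand == "-", 16L, 0L),
      reads$chrom, reads$pos, reads$aln_len,
      strrep("N", reads$aln_len), strrep("I", reads$aln_len),
      reads$NH, reads$CB, reads$UB,
      ifelse(is.na(reads$GN), "", paste0("\tGN:Z:", reads$GN))
    )
    writeLines(c(header, body), path)
  } else {
    utils::write.table(reads, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
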