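read_row <- function(pos, strand = "-", nh = 1L, chrom = "chrY", len = 98L,
                     cb = "A", ub = "u1") {
  data.frame(chrom = chrom, pos = pos, aln_len = len, strand = strand,
             NH = nh, CB = cb, UB = ub, GN = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("rescue keeps exactly the strand/NH/interval-conformant reads", {
  locus <- locus_spec()
  kept <- rescue_reads(read_row(2654000), locus)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$GN, "Sry")

  expect_equal(nrow(rescue_reads(read_row(2654000, strand = "+"), locus)), 0)
  expect_equal(nrow(rescue_reads(read_row(2654000, nh = 3L), locus)), 0)
  expect_equal(nrow(rescue_reads(read_row(2654000, nh = 2L), locus)), 1)

  # closed-interval overlap boundary: span end 2653158 misses, 2653159 hits
  expect_equal(nrow(rescue_reads(read_row(2653061), locus)), 0)
  expect_equal(nrow(rescue_reads(read_row(2653062), locus)), 1)
  # and at the right edge: start at end hits, one past misses
  expect_equal(nrow(rescue_reads(read_row(2655636), locus)), 1)
  expect_equal(nrow(rescue_reads(read_row(2655637), locus)), 0)

  expect_equal(nrow(rescue_reads(read_row(2654000, chrom = "chr1"), locus)), 0)
})

test_that("rescue preserves order, is idempotent, and honours the start-inside rule", {
  reads <- rbind(read_row(2654000, ub = "u1"), read_row(2653200, ub = "u2"),
                 read_row(2655000, ub = "u3"))
  out <- rescue_reads(reads, locus_spec())
  expect_equal(out$UB, c("u1", "u2", "u3"))
  expect_identical(rescue_reads(out, locus_spec()), out)

  # alternative membership: leftmost position inside the interval
  strict <- locus_spec(overlap = "start")
  expect_equal(nrow(rescue_reads(read_row(2653062), strict)), 0)
  expect_equal(nrow(rescue_reads(read_row(2653159), strict)), 1)
})

test_that("deduplication follows the directional adjacency rule", {
  grp <- function(ubs) {
    data.frame(chrom = "chrY", pos = 1L, aln_len = 98L, strand = "-", NH = 1L,
               CB = "A", UB = ubs, GN = "Sry", stringsAsFactors = FALSE)
  }
  # AAAA x3 absorbs AAAT x1 (3 >= 2*1 - 1, Hamming 1)
  r <- grp(c("AAAA", "AAAA", "AAAA", "AAAT"))
  expect_equal(dedup_count(r, "directional")$count, 1L)
  expect_equal(dedup_count(r, "unique")$count, 2L)

  # Hamming distance 4: two molecules under both methods
  r2 <- grp(c("AAAA", "TTTT"))
  expect_equal(dedup_count(r2, "directional")$count, 2L)
  expect_equal(dedup_count(r2, "unique")$count, 2L)

  # equal counts: 1 >= 2*1 - 1 both ways, still one cluster
  r3 <- grp(c("AAAA", "AAAT"))
  expect_equal(dedup_count(r3, "directional")$count, 1L)

  # counts 2 and 2: 2 < 2*2 - 1, no edge, two molecules
  r4 <- grp(c("AAAA", "AAAA", "AAAT", "AAAT"))
  expect_equal(dedup_count(r4, "directional")$count, 2L)

  expect_error(dedup_count(grp(c("AAAA", "AAAAA"))), "unequal length")
  expect_gte(dedup_count(grp("AAAA"))$count, 1L)
})

test_that("rescued and deduplicated counts equal simulated molecule counts exactly", {
  cfg <- sim_config(seed = 21, locus_dup_rate = 0.5, locus_mol_mean = 4,
                    locus_expr_frac = 0.8)
  cells <- sprintf("C%02d", 1:30)
  sim <- simulate_locus_reads(cfg, cells)
  rescued <- rescue_reads(sim$reads, locus_spec())
  counts <- dedup_count(rescued, "directional")
  got <- stats::setNames(rep(0L, length(cells)), cells)
  got[counts$CB] <- counts$count
  expect_equal(got, sim$truth[cells])

  # unique >= directional >= 1 on every non-empty group
  uniq <- dedup_count(rescued, "unique")
  expect_true(all(uniq$count >= counts$count))
  expect_true(all(counts$count >= 1))
})

test_that("merge_counts sets values, creates the gene row, and drops foreign barcodes", {
  m <- Matrix::Matrix(matrix(1:6, nrow = 2,
                             dimnames = list(c("g1", "g2"), c("A", "B", "C"))),
                      sparse = TRUE)
  lc <- data.frame(CB = "A", gene = "Sry", count = 2L)
  out <- merge_counts(m, lc)
  expect_true("Sry" %in% rownames(out))
  expect_equal(unname(out["Sry", ]), c(2, 0, 0))
  expect_equal(out[c("g1", "g2"), ], m)

  # empty counts: identity
  empty <- data.frame(CB = character(0), gene = character(0), count = integer(0))
  expect_identical(merge_counts(m, empty), m)

  # foreign barcode dropped with a message
  expect_message(out2 <- merge_counts(m, data.frame(CB = "Z", gene = "Sry",
                                                    count = 5L)),
                 "1 locus count")
  expect_equal(sum(out2["Sry", ]), 0)

  # set, not add; --add switches to accumulation
  out3 <- merge_counts(out, lc)
  expect_equal(out3["Sry", "A"], 2)
  out4 <- merge_counts(out, lc, add = TRUE)
  expect_equal(out4["Sry", "A"], 4)
})

test_that("read records survive a SAM round trip", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  cfg <- sim_config(seed = 22)
  sim <- simulate_locus_reads(cfg, c("AAAC", "AAAG"),
                              n_molecules = c(AAAC = 2L, AAAG = 1L))
  sam <- file.path(tempdir(), "locus_roundtrip.sam")
  write_read_records(sim$reads, sam)
  back <- read_read_records(sam)
  ord <- order(back$CB, back$UB, back$strand, back$NH)
  ord0 <- order(sim$reads$CB, sim$reads$UB, sim$reads$strand, sim$reads$NH)
  for (col in c("chrom", "pos", "strand", "NH", "CB", "UB")) {
    expect_equal(back[[col]][ord], sim$reads[[col]][ord0])
  }
})
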