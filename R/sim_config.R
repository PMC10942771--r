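#' Configuration for the synthetic gonadogenesis simulator
#'
#' Builds the parameter set shared by [simulate_droplets()],
#' [simulate_lineage()] and [simulate_locus_reads()]. The defaults encode the
#' study design the package is built around: five developmental stages
#' (E10.5--E16.5), two genetic sexes, two independent biological replicates
#' per condition, a branching somatic lineage in which a coelomic-epithelium
#' progenitor gives rise to surface epithelium, a presupporting branch that
#' resolves into Sertoli (XY) and pregranulosa (XX) fates, and a
#' supporting-like cell (SLC) branch whose sexual dimorphism appears only
#' from the third stage (E12.5) onward.
#'
#' @param seed integer seed; every generator is deterministic given the
#'   config (including this seed).
#' @param n_genes number of genes.
#' @param n_ambient_barcodes number of empty (ambient-only) droplet barcodes.
#' @param n_cells_per_population named integer vector, total cells per
#'   population across all of that population's valid stage/sex/batch
#'   conditions. Populations: CE, SE, preSup, Sertoli, Granulosa, SLC_early,
#'   SLC_late.
#' @param stages ordered character vector of 5 stage labels.
#' @param sexes character vector, the two genetic sexes.
#' @param n_batches_per_condition number of replicate batches (>= 2).
#' @param ambient_umi_logmean,ambient_umi_logsd log10-scale location/spread
#'   of ambient barcode UMI totals.
#' @param cell_umi_logmean,cell_umi_logsd log10-scale location/spread of real
#'   cell UMI totals in the droplet simulation.
#' @param lineage_umi_mean expected UMI total per cell in the lineage
#'   simulation.
#' @param nb_dispersion gamma-Poisson (negative binomial) dispersion phi;
#'   Var = mu + phi mu^2.
#' @param batch_effect_sd standard deviation of the per-gene log-scale
#'   multiplicative batch factor.
#' @param marker_block_size genes per population marker block (and per
#'   cell-cycle program).
#' @param marker_strength fold elevation of a population's own marker block.
#' @param cycle_strength fold elevation of the active cell-cycle program in a
#'   cycling cell.
#' @param cycle_quiescent_frac multiplier on both cell-cycle programs in
#'   quiescent cells (default 0.3): quiescent cells downregulate the cycle
#'   machinery rather than expressing it at baseline.
#' @param dimorphism_onset_stage_index 0-based stage index at which SLC
#'   profiles begin interpolating toward the sex-matched supporting fate
#'   (default 2, i.e. the third stage).
#' @param dimorphism_strength maximum fraction of the supporting profile
#'   mixed into late SLCs (default 0.5): differentiating SLCs acquire fate
#'   markers substantially but never reach supporting-cell expression
#'   levels.
#' @param ambient_in_cells optional fraction of each real cell's counts drawn
#'   from the ambient profile (default 0).
#' @param locus_chrom,locus_interval,locus_gene_name the palindromic locus
#'   emulated by [simulate_locus_reads()] (defaults: exon 2 of Sry,
#'   chrY:2653159-2655636).
#' @param locus_expr_frac fraction of cells expressing the locus.
#' @param locus_mol_mean mean molecules per expressing cell (Poisson).
#' @param locus_dup_rate per-read duplication rate (geometric extra copies).
#' @param locus_decoy_per_cell decoy reads (positive-strand mirrors aside)
#'   with NH >= 3 emitted per cell.
#' @param read_len,umi_len aligned read length and UMI length.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 3000L,
                       n_ambient_barcodes = 2000L,
                       n_cells_per_population = c(
                         CE = 1200L, SE = 800L, preSup = 1000L,
                         Sertoli = 700L, Granulosa = 700L,
                         SLC_early = 600L, SLC_late = 1000L
                       ),
                       stages = c("E10.5", "E11.5", "E12.5", "E13.5", "E16.5"),
                       sexes = c("XX", "XY"),
                       n_batches_per_condition = 2L,
                       ambient_umi_logmean = 1.0,
                       ambient_umi_logsd = 0.35,
                       cell_umi_logmean = 3.5,
                       cell_umi_logsd = 0.35,
                       lineage_umi_mean = 5000,
                       nb_dispersion = 0.1,
                       batch_effect_sd = 0.1,
                       marker_block_size = 50L,
                       marker_strength = 8,
                       cycle_strength = 0.5,
                       cycle_quiescent_frac = 0.3,
                       dimorphism_onset_stage_index = 2L,
                       dimorphism_strength = 0.5,
                       ambient_in_cells = 0,
                       locus_chrom = "chrY",
                       locus_interval = c(2653159L, 2655636L),
                       locus_gene_name = "Sry",
                       locus_expr_frac = 0.3,
                       locus_mol_mean = 3,
                       locus_dup_rate = 0.3,
                       locus_decoy_per_cell = 2L,
                       read_len = 98L,
                       umi_len = 10L) {
  .stopifnot_named(n_cells_per_population, "n_cells_per_population")
  stopifnot(
    length(stages) == 5L,
    n_batches_per_condition >= 1L,
    nb_dispersion > 0,
    batch_effect_sd >= 0,
    n_genes >= 10L * marker_block_size,
    dimorphism_onset_stage_index >= 0L,
    dimorphism_onset_stage_index <= 4L,
    dimorphism_strength >= 0, dimorphism_strength <= 1,
    all(n_cells_per_population >= 0),
    n_ambient_barcodes >= 0L,
    locus_interval[1] <= locus_interval[2],
    ambient_in_cells >= 0, ambient_in_cells < 1
  )
  if (cell_umi_logmean <= ambient_umi_logmean) {
    stop("cell_umi_logmean must exceed ambient_umi_logmean (separable modes)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Populations and lineage tree (child -> parent).
.sim_populations <- c("CE", "SE", "preSup", "Sertoli", "Granulosa",
                      "SLC_early", "SLC_late")

.sim_tree <- c(
  CE = NA_character_, SE = "CE", preSup = "CE",
  Sertoli = "preSup", Granulosa = "preSup",
  SLC_early = "CE", SLC_late = "SLC_early"
)

# Valid 0-based stage indices and sexes per population.
.sim_validity <- function(config) {
  sexes <- config$sexes
  list(
    CE        = list(stages = 0:4, sexes = sexes),
    SE        = list(stages = 0:4, sexes = sexes),
    preSup    = list(stages = 0:4, sexes = sexes),
    Sertoli   = list(stages = 2:4, sexes = "XY"),
    Granulosa = list(stages = 2:4, sexes = "XX"),
    SLC_early = list(stages = 0:1, sexes = sexes),
    SLC_late  = list(stages = 2:4, sexes = sexes)
  )
}

.sim_gene_ids <- function(n_genes) {
  sprintf("Gene%05d", seq_len(n_genes))
}

# Deterministic unique barcode sequences: integer index -> base-4 ACGT word.
.sim_barcodes <- function(n, width = 16L) {
  stopifnot(n < 4^width)
  alph <- c("A", "C", "G", "T")
  idx <- seq_len(n) - 1L
  mat <- matrix("A", nrow = n, ncol = width)
  for (j in seq_len(width)) {
    mat[, width - j + 1L] <- alph[(idx %% 4L) + 1L]
    idx <- idx %/% 4L
  }
  apply(mat, 1L, paste0, collapse = "")
}

# Gene-program and marker-block index layout, deterministic in n_genes and
# block size: blocks tile the first genes, cell-cycle programs follow.
.sim_blocks <- function(config) {
  b <- config$marker_block_size
  pops <- .sim_populations
  blocks <- list()
  at <- 1L
  for (p in pops) {
    blocks[[p]] <- seq.int(at, length.out = b)
    at <- at + b
  }
  blocks$S <- seq.int(at, length.out = b); at <- at + b
  blocks$G2M <- seq.int(at, length.out = b)
  blocks
}

# Generating mean profiles (expected UMIs per gene per cell, before batch
# factors), one per (population, stage index, sex) that the design allows.
# Marker blocks are elevated on the population itself and, more weakly, on
# its direct descendants, giving tree-correlated transcriptomes. SLC_late
# interpolates toward the sex-matched supporting profile for stages at or
# after the dimorphism onset, except on the SLC marker blocks which the
# lineage retains throughout.
.sim_profiles <- function(config) {
  blocks <- .sim_blocks(config)
  n <- config$n_genes
  base <- stats::rgamma(n, shape = 0.6, rate = 1) + 0.05

  pop_profile <- function(pop) {
    prof <- base
    prof[blocks[[pop]]] <- prof[blocks[[pop]]] * config$marker_strength
    parent <- .sim_tree[[pop]]
    while (!is.na(parent)) {
      prof[blocks[[parent]]] <-
        prof[blocks[[parent]]] * sqrt(config$marker_strength)
      parent <- .sim_tree[[parent]]
    }
    prof
  }
  raw <- lapply(.sim_populations, pop_profile)
  names(raw) <- .sim_populations

  onset <- config$dimorphism_onset_stage_index
  slc_blocks <- c(blocks$SLC_early, blocks$SLC_late)
  profiles <- list()
  valid <- .sim_validity(config)
  for (pop in .sim_populations) {
    for (s in valid[[pop]]$stages) {
      for (sex in valid[[pop]]$sexes) {
        prof <- raw[[pop]]
        if (pop == "SLC_late" && s >= onset) {
          w <- max(0, (s - onset + 1) / (5 - onset)) * config$dimorphism_strength
          fate <- if (sex == "XY") raw$Sertoli else raw$Granulosa
          mixed <- (1 - w) * prof + w * fate
          mixed[slc_blocks] <- prof[slc_blocks]
          prof <- mixed
        }
        key <- paste(pop, s, sex, sep = "|")
        profiles[[key]] <- prof / sum(prof) * config$lineage_umi_mean
      }
    }
  }
  list(profiles = profiles, blocks = blocks, base = base)
}

.profile_key <- function(pop, stage_idx, sex) paste(pop, stage_idx, sex, sep = "|")
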