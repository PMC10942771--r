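#' Simulate a branching gonadal lineage with ground truth
#'
#' Draws a genes x cells gamma-Poisson (negative binomial) count matrix whose
#' population mean profiles follow the branching somatic lineage of the
#' developing gonad: a coelomic-epithelium (CE) progenitor gives rise to the
#' surface epithelium, to a presupporting branch that resolves into Sertoli
#' (XY) and pregranulosa (XX) fates, and to a supporting-like cell (SLC)
#' branch. SLC-late mean profiles interpolate toward the sex-matched
#' supporting fate only from `dimorphism_onset_stage_index` onward, with
#' interpolation weight `w = (stage - onset + 1) / (5 - onset)`; the SLC
#' marker blocks are retained un-interpolated so the lineage keeps its own
#' identity while acquiring fate markers. Replicate batches multiply every
#' gene by a log-normal factor. Cells of cycling populations (CE, SE,
#' Sertoli, Granulosa) receive an S- or G2M-program elevation; presupporting
#' and SLC cells are quiescent and receive none.
#'
#' @param config a [sim_config()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, colData columns `stage`, `sex`, `batch`, `population`,
#'   `cycling`, `phase`, and `metadata()$truth` holding the generating mean
#'   profiles, per-batch gene factors, marker/signature gene sets and the
#'   S/G2M program genes.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_lineage_impl(config))
}

.lineage_cell_table <- function(config) {
  valid <- .sim_validity(config)
  rows <- list()
  for (pop in names(config$n_cells_per_population)) {
    if (!pop %in% .sim_populations) {
      stop("unknown population in tree: ", pop)
    }
    n_total <- config$n_cells_per_population[[pop]]
    if (n_total == 0) next
    combos <- expand.grid(
      stage_idx = valid[[pop]]$stages,
      sex = valid[[pop]]$sexes,
      batch = seq_len(config$n_batches_per_condition),
      stringsAsFactors = FALSE
    )
    n_each <- rep(n_total %/% nrow(combos), nrow(combos))
    rem <- n_total %% nrow(combos)
    if (rem > 0) n_each[seq_len(rem)] <- n_each[seq_len(rem)] + 1L
    combos$n <- n_each
    combos$population <- pop
    rows[[pop]] <- combos[combos$n > 0, , drop = FALSE]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

.simulate_lineage_impl <- function(config) {
  prof <- .sim_profiles(config)
  tab <- .lineage_cell_table(config)
  n_genes <- config$n_genes
  gene_ids <- .sim_gene_ids(n_genes)
  size <- 1 / config$nb_dispersion

  batch_levels <- paste0("b", seq_len(config$n_batches_per_condition))
  batch_factors <- vapply(
    batch_levels,
    function(b) exp(stats::rnorm(n_genes, 0, config$batch_effect_sd)),
    numeric(n_genes)
  )
  rownames(batch_factors) <- gene_ids

  cycling_pops <- c("CE", "SE", "Sertoli", "Granulosa")
  s_idx <- prof$blocks$S
  g2m_idx <- prof$blocks$G2M

  meta <- list()
  mats <- list()
  cell_counter <- 0L
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    mu <- prof$profiles[[.profile_key(row$population, row$stage_idx, row$sex)]]
    mu <- mu * batch_factors[, row$batch]
    n_cells <- row$n

    is_cycling <- row$population %in% cycling_pops
    phase <- if (is_cycling) {
      sample(c("S", "G2M"), n_cells, replace = TRUE)
    } else {
      rep("G0", n_cells)
    }

    m <- matrix(0L, nrow = n_genes, ncol = n_cells)
    for (ph in unique(phase)) {
      cols <- which(phase == ph)
      mu_ph <- mu
      if (ph == "G0") {
        mu_ph[c(s_idx, g2m_idx)] <- mu_ph[c(s_idx, g2m_idx)] * config$cycle_quiescent_frac
      }
      if (ph == "S") mu_ph[s_idx] <- mu_ph[s_idx] * (1 + config$cycle_strength)
      if (ph == "G2M") mu_ph[g2m_idx] <- mu_ph[g2m_idx] * (1 + config$cycle_strength)
      m[, cols] <- stats::rnbinom(n_genes * length(cols),
                                  mu = rep(mu_ph, length(cols)), size = size)
    }
    mats[[i]] <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    meta[[i]] <- data.frame(
      stage = config$stages[row$stage_idx + 1L],
      stage_idx = row$stage_idx,
      sex = row$sex,
      batch = batch_levels[row$batch],
      population = row$population,
      cycling = is_cycling,
      phase = phase,
      stringsAsFactors = FALSE
    )
    cell_counter <- cell_counter + n_cells
  }

  counts <- do.call(cbind, mats)
  cd <- do.call(rbind, meta)
  cd$barcode <- .sim_barcodes(nrow(cd))
  rownames(cd) <- cd$barcode
  dimnames(counts) <- list(gene_ids, cd$barcode)

  blocks <- prof$blocks
  truth <- list(
    mean_profiles = prof$profiles,
    batch_factors = batch_factors,
    marker_blocks = lapply(blocks, function(ix) gene_ids[ix]),
    signature_genes = list(
      Sertoli = gene_ids[blocks$Sertoli],
      Granulosa = gene_ids[blocks$Granulosa],
      SLC = gene_ids[c(blocks$SLC_early, blocks$SLC_late)]
    ),
    s_genes = gene_ids[blocks$S],
    g2m_genes = gene_ids[blocks$G2M]
  )

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(truth = truth, config = config)
  )
}

#' True differentially expressed genes between two simulated populations
#'
#' Reads the generating mean profiles recorded by [simulate_lineage()] and
#' returns the genes whose means differ between two populations at a given
#' stage and sex, optionally restricted to fold changes exceeding a cutoff
#' (on the natural-log scale of the mean).
#'
#' @param sce result of [simulate_lineage()].
#' @param pop_a,pop_b population labels.
#' @param stage_idx 0-based stage index at which to compare.
#' @param sex sex label.
#' @param min_lfc minimum |log mean ratio| for a gene to count as truly DE.
#' @return character vector of gene ids.
#' @export
true_de_genes <- function(sce, pop_a, pop_b, stage_idx, sex, min_lfc = 0) {
  truth <- S4Vectors::metadata(sce)$truth
  a <- truth$mean_profiles[[.profile_key(pop_a, stage_idx, sex)]]
  b <- truth$mean_profiles[[.profile_key(pop_b, stage_idx, sex)]]
  if (is.null(a) || is.null(b)) stop("no generating profile for that condition")
  lfc <- abs(log(a) - log(b))
  rownames(sce)[lfc > min_lfc]
}
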