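#' Simulate raw droplet data with ambient and real-cell barcodes
#'
#' Emulates the input to droplet cell calling: a barcode x gene count matrix
#' whose ranked UMI totals are bimodal. Ambient barcodes draw their totals
#' from a low log-normal mode and distribute them over a flat (uniform) gene
#' profile; real cells draw totals from a high log-normal mode and distribute
#' them over their population's mean profile. Counts are multinomial given
#' the total, so the sum of matrix entries equals the sum of sampled totals
#' exactly.
#'
#' @param config a [sim_config()]. `n_ambient_barcodes` ambient barcodes are
#'   generated; real cells total `sum(n_cells_per_population)` and are
#'   assigned populations in proportion to that map.
#' @return list with elements
#'   \item{counts}{genes x barcodes sparse integer matrix (cells first).}
#'   \item{truth}{list: `is_cell` named logical, `population` per-cell
#'     labels, `totals` the sampled per-barcode totals, `boundary_total` the
#'     midpoint separating the configured modes (log10 scale).}
#'   \item{nonseparable}{TRUE when the configured modes overlap beyond
#'     tolerance (separation below 2 combined standard deviations); the
#'     simulation still runs, this is a warning flag.}
#' @export
simulate_droplets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_droplets_impl(config))
}

.simulate_droplets_impl <- function(config) {
  n_genes <- config$n_genes
  gene_ids <- .sim_gene_ids(n_genes)
  prof <- .sim_profiles(config)

  n_cells <- sum(config$n_cells_per_population)
  n_amb <- config$n_ambient_barcodes
  pops <- names(config$n_cells_per_population)
  population <- rep(pops, times = config$n_cells_per_population)

  cell_totals <- if (n_cells > 0) {
    pmax(1L, as.integer(round(10^stats::rnorm(
      n_cells, config$cell_umi_logmean, config$cell_umi_logsd
    ))))
  } else integer(0)
  amb_totals <- if (n_amb > 0) {
    as.integer(round(10^stats::rnorm(
      n_amb, config$ambient_umi_logmean, config$ambient_umi_logsd
    )))
  } else integer(0)

  ambient_prob <- rep(1 / n_genes, n_genes)
  # Base (stage-independent) population profiles for droplet cells: the
  # earliest valid stage of each population, first listed sex.
  valid <- .sim_validity(config)
  base_prob <- lapply(pops, function(p) {
    key <- .profile_key(p, valid[[p]]$stages[1], valid[[p]]$sexes[1])
    pr <- prof$profiles[[key]]
    pr / sum(pr)
  })
  names(base_prob) <- pops

  f <- config$ambient_in_cells
  draw <- function(total, prob) {
    if (total == 0) integer(n_genes) else as.integer(stats::rmultinom(1, total, prob))
  }
  cols <- vector("list", n_cells + n_amb)
  for (i in seq_len(n_cells)) {
    prob <- (1 - f) * base_prob[[population[i]]] + f * ambient_prob
    cols[[i]] <- draw(cell_totals[i], prob)
  }
  for (i in seq_len(n_amb)) {
    cols[[n_cells + i]] <- draw(amb_totals[i], ambient_prob)
  }
  counts <- methods::as(
    Matrix::Matrix(matrix(unlist(cols), nrow = n_genes), sparse = TRUE),
    "CsparseMatrix"
  )
  barcodes <- .sim_barcodes(n_cells + n_amb)
  dimnames(counts) <- list(gene_ids, barcodes)

  is_cell <- c(rep(TRUE, n_cells), rep(FALSE, n_amb))
  names(is_cell) <- barcodes
  population_named <- c(population, rep(NA_character_, n_amb))
  names(population_named) <- barcodes

  sep <- (config$cell_umi_logmean - config$ambient_umi_logmean) /
    sqrt(config$cell_umi_logsd^2 + config$ambient_umi_logsd^2)

  list(
    counts = counts,
    truth = list(
      is_cell = is_cell,
      population = population_named,
      totals = stats::setNames(c(cell_totals, amb_totals), barcodes),
      boundary_total = 10^((config$cell_umi_logmean + config$ambient_umi_logmean) / 2)
    ),
    nonseparable = sep < 2
  )
}
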