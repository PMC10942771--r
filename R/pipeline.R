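#' Pipeline run configuration
#'
#' Bundles every stage's parameters with a single global seed. Defaults
#' mirror the analysis the package implements: Leiden resolution 1.3,
#' restricted subclustering at 0.37, genes kept when expressed in more than
#' 50 cells, 100 ICA components, scale factor 10,000 with 5% high-expressor
#' exclusion, DE thresholds logFC > 0.25 and adjusted p < 0.05, 300 cells
#' per cluster for signature training, and the Sry exon-2 locus rescue
#' (chrY:2653159-2655636, negative strand, NH < 3).
#'
#' @param seed global seed; stage seeds derive from it.
#' @param sim [sim_config()] for the lineage simulation.
#' @param droplet_sim [sim_config()] for the droplet (cell-calling) stage.
#' @param n_components ICA components.
#' @param k_per_batch batch-balanced kNN neighbors per batch.
#' @param resolution,subcluster_resolution Leiden resolutions.
#' @param min_gene_cells gene filter cutoff (strict).
#' @param min_cluster_size cluster-graph removal cutoff.
#' @param n_per_cluster signature-training subsample size.
#' @param de a [de_params()].
#' @param locus a [locus_spec()].
#' @param tenx_dir,reads_path optional paths to existing inputs; when set
#'   they replace the corresponding simulation stage and must exist.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            droplet_sim = sim_config(
                              seed = seed + 1L,
                              n_genes = 1000L,
                              n_ambient_barcodes = 2000L,
                              n_cells_per_population = c(CE = 300L, preSup = 200L)
                            ),
                            n_components = 100L,
                            k_per_batch = 3L,
                            resolution = 1.3,
                            subcluster_resolution = 0.37,
                            min_gene_cells = 50L,
                            min_cluster_size = 50L,
                            n_per_cluster = 300L,
                            de = de_params(),
                            locus = locus_spec(),
                            tenx_dir = NULL,
                            reads_path = NULL) {
  cfg <- as.list(environment())
  for (field in c("tenx_dir", "reads_path")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline_config: path for field '", field, "' does not exist: ", p)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate, callcells, rescue, normalize, cluster, lineage, de and
#' score in order, writing each stage's tabular outputs plus a manifest
#' (stage, parameters, seed, output MD5 hashes) to `out_dir`. Rerunning with
#' the same config reproduces byte-identical outputs; one log line per stage
#' reports cells, genes and wall time.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  t_all <- proc.time()[3]

  log_stage <- function(name, t0, n_cells, n_genes, files) {
    message(sprintf("[%s] seed=%d cells=%d genes=%d wall=%.1fs",
                    name, config$seed, n_cells, n_genes,
                    proc.time()[3] - t0))
    manifest[[length(manifest) + 1L]] <<- list(
      stage = name, seed = config$seed, n_cells = n_cells, n_genes = n_genes,
      outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                                basename(files))
    )
  }

  # -- simulate ---------------------------------------------------------
  t0 <- proc.time()[3]
  drop <- simulate_droplets(config$droplet_sim)
  sce <- simulate_lineage(config$sim)
  counts <- SummarizedExperiment::assay(sce, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  locus_sim <- simulate_locus_reads(config$sim, colnames(counts))
  f_meta <- file.path(out_dir, "cell_metadata.tsv")
  utils::write.table(meta, f_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  f_reads <- file.path(out_dir, "locus_reads.tsv")
  write_read_records(locus_sim$reads, f_reads)
  log_stage("simulate", t0, ncol(counts), nrow(counts), c(f_meta, f_reads))

  # -- callcells --------------------------------------------------------
  t0 <- proc.time()[3]
  call <- call_cells(drop$counts)
  f_called <- file.path(out_dir, "called_barcodes.tsv")
  writeLines(call$called_barcodes, f_called)
  f_call <- file.path(out_dir, "cell_calling.json")
  jsonlite::write_json(
    list(knee = call$knee_total, inflection = call$inflection_total,
         threshold = call$threshold_total, used_fallback = call$used_fallback,
         n_called = length(call$called_barcodes)),
    f_call, auto_unbox = TRUE, digits = NA
  )
  log_stage("callcells", t0, length(call$called_barcodes),
            nrow(drop$counts), c(f_called, f_call))

  # -- rescue -----------------------------------------------------------
  t0 <- proc.time()[3]
  rescued <- rescue_reads(locus_sim$reads, config$locus)
  locus_counts <- dedup_count(rescued)
  counts <- merge_counts(counts, locus_counts, config$locus$gene_name)
  f_locus <- file.path(out_dir, "locus_counts.tsv")
  utils::write.table(locus_counts, f_locus, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("rescue", t0, ncol(counts), nrow(counts), f_locus)

  # -- normalize --------------------------------------------------------
  t0 <- proc.time()[3]
  lognorm <- normalize_counts(counts)
  genes_keep <- gene_filter(counts, config$min_gene_cells)
  f_norm <- file.path(out_dir, "normalization.json")
  jsonlite::write_json(
    list(scale = 1e4, high_frac = 0.05, log_base = "natural",
         n_genes_filtered = length(genes_keep)),
    f_norm, auto_unbox = TRUE, digits = NA
  )
  log_stage("normalize", t0, ncol(lognorm), length(genes_keep), f_norm)

  # -- cluster ----------------------------------------------------------
  t0 <- proc.time()[3]
  emb <- ica_embed(lognorm[genes_keep, ],
                   n_components = min(config$n_components,
                                      length(genes_keep), ncol(lognorm)),
                   seed = config$seed)
  graph <- batch_balanced_knn(emb, meta$batch, config$k_per_batch)
  labels <- leiden_cluster(graph, resolution = config$resolution,
                           seed = config$seed)
  f_labels <- file.path(out_dir, "cluster_labels.tsv")
  utils::write.table(data.frame(cell = names(labels), label = labels),
                     f_labels, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cluster", t0, length(labels), length(genes_keep), f_labels)

  # -- lineage ----------------------------------------------------------
  t0 <- proc.time()[3]
  cg <- paga_graph(graph, labels, min_cluster_size = config$min_cluster_size,
                   seed = config$seed)
  ord <- correlation_order(lognorm[genes_keep, ], labels)
  truth <- S4Vectors::metadata(sce)$truth
  cc <- cell_cycle_phase(lognorm, truth$s_genes, truth$g2m_genes,
                         seed = config$seed)
  f_edges <- file.path(out_dir, "cluster_graph.tsv")
  utils::write.table(cg$edges, f_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_order <- file.path(out_dir, "cluster_order.tsv")
  utils::write.table(data.frame(order = ord$order), f_order, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f_cc <- file.path(out_dir, "cell_cycle.tsv")
  utils::write.table(cc, f_cc, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("lineage", t0, length(labels), length(genes_keep),
            c(f_edges, f_order, f_cc))

  # -- de ---------------------------------------------------------------
  t0 <- proc.time()[3]
  slc_late <- rownames(meta)[meta$population == "SLC_late" & meta$sex == "XY"]
  sertoli <- rownames(meta)[meta$population == "Sertoli"]
  de <- hurdle_test(lognorm[genes_keep, ], slc_late, sertoli, config$de)
  f_de <- file.path(out_dir, "de_slc_vs_sertoli.tsv")
  utils::write.table(format(de, digits = 10), f_de, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_stage("de", t0, length(slc_late) + length(sertoli), nrow(de), f_de)

  # -- score ------------------------------------------------------------
  t0 <- proc.time()[3]
  pop_labels <- stats::setNames(meta$population, rownames(meta))
  sub <- balanced_subsample(pop_labels, config$n_per_cluster,
                            seed = config$seed)
  models <- lapply(c(Sertoli = "Sertoli", Granulosa = "Granulosa"),
                   function(cl) train_signature(lognorm[genes_keep, sub],
                                                pop_labels[sub], cl,
                                                seed = config$seed))
  scores <- lapply(models, score_cells, lognorm = lognorm[genes_keep, ])
  tables <- lapply(scores, summarize_scores, cell_meta = meta)
  f_model <- file.path(out_dir, "signature_models.json")
  jsonlite::write_json(
    lapply(models, function(m) list(target_class = m$target_class,
                                    intercept = m$intercept,
                                    weights = as.list(m$weights),
                                    lambda = m$lambda, seed = m$seed)),
    f_model, auto_unbox = TRUE, digits = NA
  )
  f_scores <- file.path(out_dir, "score_tables.tsv")
  tab_out <- do.call(rbind, lapply(names(tables), function(nm) {
    cbind(signature = nm, tables[[nm]])
  }))
  utils::write.table(format(tab_out, digits = 10), f_scores, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("score", t0, length(sub), length(genes_keep),
            c(f_model, f_scores))

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
  message(sprintf("pipeline complete: %d stages, %.1fs total",
                  length(manifest), proc.time()[3] - t_all))
  invisible(list(
    manifest = manifest, call = call, sce = sce, lognorm = lognorm,
    genes = genes_keep, embedding = emb, graph = graph, labels = labels,
    cluster_graph = cg, order = ord, cell_cycle = cc, de = de,
    models = models, scores = scores, score_tables = tables
  ))
}

#' Per-cell quality-control metrics
#'
#' Reports (never filters on) per-cell totals, detected genes, and
#' mitochondrial/ribosomal count fractions identified by gene-name prefix.
#' The report always has one row per cell.
#'
#' @param counts genes x cells count matrix.
#' @param mito_prefix prefix marking mitochondrial genes (default "mt-").
#' @param ribo_prefix prefixes marking ribosomal protein genes.
#' @return data.frame with `cell`, `total_umis`, `detected_genes`,
#'   `mito_fraction`, `ribo_fraction`.
#' @export
qc_report <- function(counts, mito_prefix = "mt-",
                      ribo_prefix = c("Rps", "Rpl")) {
  genes <- rownames(counts)
  totals <- Matrix::colSums(counts)
  mito <- startsWith(genes, mito_prefix)
  ribo <- Reduce(`|`, lapply(ribo_prefix, startsWith, x = genes))
  frac <- function(mask) {
    if (!any(mask)) return(rep(0, ncol(counts)))
    ifelse(totals == 0, 0,
           Matrix::colSums(counts[mask, , drop = FALSE]) / totals)
  }
  data.frame(
    cell = colnames(counts),
    total_umis = unname(totals),
    detected_genes = unname(Matrix::colSums(counts > 0)),
    mito_fraction = unname(frac(mito)),
    ribo_fraction = unname(frac(ribo)),
    stringsAsFactors = FALSE
  )
}
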