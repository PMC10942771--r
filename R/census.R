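# Bundled census tables from the developing-gonad atlas and its
# lineage-tracing quantification; shipped so the headline percentages and
# totals can be recomputed from raw counts.

.census_table <- function(name) {
  utils::read.table(
    system.file("extdata", paste0(name, ".tsv"), package = "slcatlas",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
}

#' Lineage-tracing co-expression percentages
#'
#' Recomputes, from the raw immunofluorescence cell counts, the percentage
#' of marker-positive supporting cells (AMH+ Sertoli, FOXL2+ granulosa) that
#' also carry the Pax8-lineage reporter:
#' `100 * double_positive / (double_positive + marker_only)`.
#'
#' @return data.frame with `fate`, `marker`, the raw counts, and `percent`.
#' @export
coexpression_percentages <- function() {
  tab <- .census_table("coexpression_counts")
  tab$percent <- 100 * tab$double_positive /
    (tab$double_positive + tab$marker_only)
  tab
}

#' Supporting-like cell census totals
#'
#' Recomputes the early (E11.5), late (E12.5-E16.5) and overall
#' supporting-like cell totals from the per-sex, per-group counts.
#'
#' @return list with `by_group` (data.frame: group, n), `total`.
#' @export
slc_census <- function() {
  tab <- .census_table("slc_census")
  by_group <- stats::aggregate(n_cells ~ group, tab, sum)
  names(by_group) <- c("group", "n")
  list(by_group = by_group, total = sum(tab$n_cells))
}

#' Atlas cell total
#'
#' Recomputes the total number of cells in the atlas from the per-stage
#' counts.
#'
#' @return list with `by_stage` (data.frame) and `total`.
#' @export
atlas_census <- function() {
  tab <- .census_table("stage_census")
  list(by_stage = tab, total = sum(tab$n_cells))
}
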