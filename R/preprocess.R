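#' Remove organelle and metazoan ASVs
#'
#' Drops the reads that do not belong to the communities under study before
#' any downstream analysis: chloroplast/mitochondrial ASVs from 16S tables
#' and metazoan (zooplankton) ASVs from 18S tables. Counts of the remaining
#' ASVs are untouched; an empty result is permitted. This step runs *before*
#' rare-ASV filtering in the pipeline.
#'
#' @param x An `asv_table` with flags populated (from input columns or
#'   [derive_flags()]).
#' @return The filtered `asv_table`.
#' @export
remove_excluded_taxa <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  drop <- if (x$marker == "16S") x$flags$is_organelle else x$flags$is_metazoan
  subset_asvs(x, !drop)
}

#' Filter rare ASVs by total abundance
#'
#' Retains exactly the ASVs whose read total across all timepoints is at
#' least `min_total`: removal is by strict `< min_total`, so an ASV sitting
#' exactly on the boundary survives. Conventional thresholds for bloom
#' amplicon series are 100 reads for 16S and 500 for 18S. Idempotent and
#' monotone in `min_total`.
#'
#' @param x An `asv_table`.
#' @param min_total Non-negative integer threshold on the row sum.
#' @return The filtered `asv_table`.
#' @export
filter_rare <- function(x, min_total) {
  stopifnot(inherits(x, "asv_table"))
  if (min_total < 0) stop("min_total must be >= 0")
  subset_asvs(x, rowSums(x$counts) >= min_total)
}

#' Relative abundance matrix
#'
#' Converts counts to per-timepoint proportions: each column is divided by
#' its sum, so columns sum to 1 within 1e-12.
#'
#' @param x An `asv_table`.
#' @return Numeric ASV x timepoint matrix of proportions.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  tot <- colSums(x$counts)
  zero <- which(tot == 0)
  if (length(zero) > 0L) {
    stop("timepoint ", colnames(x$counts)[zero[1L]],
         " has zero total counts; cannot form proportions")
  }
  sweep(x$counts, 2L, tot, "/")
}

#' Lineage relative-abundance series
#'
#' Rolls relative abundances up to one lineage: the per-timepoint sum of the
#' proportions of all ASVs whose taxonomy matches `name` at `rank`, plus its
#' mean over timepoints. An absent lineage yields an all-zero series with a
#' warning (not an error), so screening loops stay robust.
#'
#' @param x An `asv_table`.
#' @param rank One of [tax_ranks()].
#' @param name Lineage name to match exactly at that rank.
#' @return A list with `series` (named numeric, one value per timepoint),
#'   `mean`, `rank`, `name` and `n_asv` (number of matching ASVs).
#' @export
aggregate_lineage <- function(x, rank, name) {
  stopifnot(inherits(x, "asv_table"))
  if (!rank %in% tax_ranks()) stop("unknown rank: ", rank)
  rel <- relative_abundance(x)
  hit <- x$taxonomy[[rank]] == name
  if (!any(hit)) {
    warning("lineage '", name, "' not present at rank '", rank, "'")
    series <- setNames(rep(0, ncol(rel)), colnames(rel))
  } else {
    series <- colSums(rel[hit, , drop = FALSE])
  }
  list(series = series, mean = mean(series), rank = rank, name = name,
       n_asv = sum(hit))
}
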