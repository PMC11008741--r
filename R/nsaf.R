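#' Normalized spectral abundance factor (NSAF)
#'
#' Per-sample relative protein abundance: the spectral abundance factor of a
#' group is its exclusive unique spectrum count divided by the length of the
#' longest protein in the group, `SAF[g, s] = counts[g, s] / length[g]`, and
#' NSAF renormalises SAF within each sample, `NSAF[g, s] = SAF[g, s] /
#' sum_g SAF[g, s]`, so every sample column sums to 1.
#'
#' @param x A `protein_group_table`; every sample must contain at least one
#'   non-zero spectrum count.
#' @return Numeric group x sample matrix of NSAF values (columns sum to 1
#'   within 1e-9).
#' @export
nsaf <- function(x) {
  validate_protein_group_table(x)
  saf <- x$counts / x$longest_length
  tot <- colSums(saf)
  zero <- which(tot == 0)
  if (length(zero) > 0L) {
    stop("sample '", colnames(x$counts)[zero[1L]],
         "' has no spectra; NSAF undefined")
  }
  sweep(saf, 2L, tot, "/")
}

#' NSAF share of one lineage
#'
#' Sums NSAF over the groups matching a lineage, per sample, optionally
#' averaging across samples. Replicates sharing a timepoint can be averaged
#' first, so that "mean over all timepoints" weights each timepoint equally
#' regardless of replicate count.
#'
#' @param nsaf_matrix Output of [nsaf()].
#' @param x The `protein_group_table` the matrix was computed from.
#' @param lineage Lineage name to match (absent lineage gives share 0).
#' @param rank `"phylum"` (default) or `"domain"`.
#' @param average `"per_sample"` (default) returns one share per sample;
#'   `"over_all_samples"` returns their unweighted mean.
#' @param replicates_first When averaging over all samples, first average
#'   replicates within each timepoint (samples labelled `d<day>_r<rep>`),
#'   then average the timepoint means. Default `TRUE`.
#' @return Named numeric vector of per-sample shares, or a single mean share.
#' @export
taxon_share <- function(nsaf_matrix, x, lineage, rank = c("phylum", "domain"),
                        average = c("per_sample", "over_all_samples"),
                        replicates_first = TRUE) {
  rank <- match.arg(rank)
  average <- match.arg(average)
  hit <- x$taxonomy[[rank]] == lineage
  shares <- colSums(nsaf_matrix[hit, , drop = FALSE])
  if (average == "per_sample") return(shares)
  day <- sub("^d([0-9]+)_r[0-9]+$", "\\1", names(shares))
  if (replicates_first && !anyNA(day) && !all(day == names(shares))) {
    shares <- tapply(shares, day, mean)
  }
  mean(shares)
}

#' Fraction of a lineage's proteome in one function category
#'
#' Abundance-weighted (not group-count) fraction: NSAF mass of the lineage's
#' groups in the category divided by the lineage's total NSAF mass, pooled
#' across all samples. This is the "what share of a taxon's expressed
#' proteome is pathway X" statistic (e.g. the share of a sulfate-reducer
#' guild's proteome made of dissimilatory sulfate reduction enzymes).
#'
#' @param nsaf_matrix Output of [nsaf()].
#' @param x The `protein_group_table`.
#' @param lineage Lineage name (must carry non-zero NSAF mass).
#' @param function_category Category label to match exactly.
#' @param rank `"phylum"` (default) or `"domain"`.
#' @return A proportion in `[0, 1]`.
#' @export
within_taxon_function_fraction <- function(nsaf_matrix, x, lineage,
                                           function_category,
                                           rank = c("phylum", "domain")) {
  rank <- match.arg(rank)
  in_lineage <- x$taxonomy[[rank]] == lineage
  lineage_mass <- sum(nsaf_matrix[in_lineage, , drop = FALSE])
  if (lineage_mass == 0) {
    stop("lineage '", lineage, "' carries no NSAF mass")
  }
  in_cat <- in_lineage & x$function_category == function_category
  sum(nsaf_matrix[in_cat, , drop = FALSE]) / lineage_mass
}

#' Filter protein groups to validly detected ones
#'
#' Keeps groups with at least `min_peptides` matched peptides and, when
#' identification probability columns are present, probabilities at or above
#' the protein and peptide thresholds. The peptide-count rule is always
#' enforced; probability filtering only applies where probabilities exist.
#' The active thresholds are recorded on the result as attribute
#' `detection_thresholds`.
#'
#' @param x A `protein_group_table`.
#' @param min_peptides Minimum matched peptides, default 2.
#' @param protein_threshold Minimum protein identification probability,
#'   default 0.99.
#' @param peptide_threshold Minimum peptide identification probability,
#'   default 0.95.
#' @return The filtered `protein_group_table`.
#' @export
valid_detection_filter <- function(x, min_peptides = 2L,
                                   protein_threshold = 0.99,
                                   peptide_threshold = 0.95) {
  validate_protein_group_table(x)
  keep <- x$n_peptides >= min_peptides
  if (!is.null(x$protein_prob)) keep <- keep & x$protein_prob >= protein_threshold
  if (!is.null(x$peptide_prob)) keep <- keep & x$peptide_prob >= peptide_threshold
  out <- protein_group_table(
    counts = x$counts[keep, , drop = FALSE],
    longest_length = x$longest_length[keep],
    taxonomy = x$taxonomy[keep, , drop = FALSE],
    function_category = x$function_category[keep],
    n_peptides = x$n_peptides[keep],
    protein_prob = if (is.null(x$protein_prob)) NULL else x$protein_prob[keep],
    peptide_prob = if (is.null(x$peptide_prob)) NULL else x$peptide_prob[keep]
  )
  attr(out, "detection_thresholds") <- list(
    min_peptides = min_peptides, protein_threshold = protein_threshold,
    peptide_threshold = peptide_threshold
  )
  out
}
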