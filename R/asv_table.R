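#' Taxonomic ranks used throughout the package
#'
#' Ordered lineage ranks carried by ASV tables, network nodes and protein
#' groups. Ranks may be empty strings where a classifier did not resolve them.
#'
#' @return Character vector of rank names, most to least inclusive.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

.asv_flag_names <- c("is_organelle", "is_metazoan", "is_benthic")

#' Construct an ASV count table
#'
#' An `asv_table` holds a marker-tagged (16S or 18S) ASV-by-timepoint count
#' matrix together with per-ASV taxonomy lineages and exclusion flags. It is
#' the unit of data that the preprocessing and network stages operate on.
#'
#' @param counts Non-negative integer matrix, one row per ASV, one column per
#'   timepoint. Row names are ASV identifiers; column names are integer Julian
#'   day labels in strictly increasing order.
#' @param marker `"16S"` or `"18S"`; uniform for the whole table.
#' @param taxonomy Data frame with one row per ASV and the columns of
#'   [tax_ranks()] (character; empty string for unassigned ranks). Defaults to
#'   all-empty lineages.
#' @param flags Data frame with logical columns `is_organelle`, `is_metazoan`,
#'   `is_benthic`, one row per ASV. Defaults to all `FALSE`.
#'
#' @return An object of class `asv_table`: a list with elements `marker`,
#'   `counts`, `taxonomy`, `flags`. Timepoints are available via
#'   [timepoints()], ASV ids via `rownames(x$counts)`.
#' @export
asv_table <- function(counts, marker, taxonomy = NULL, flags = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"   # validated as whole numbers below
  n <- nrow(counts)
  if (is.null(taxonomy)) {
    taxonomy <- as.data.frame(
      setNames(rep(list(character(n)), length(tax_ranks())), tax_ranks()),
      stringsAsFactors = FALSE
    )
    taxonomy[] <- lapply(taxonomy, function(col) rep("", n))
  }
  if (is.null(flags)) {
    flags <- as.data.frame(
      setNames(rep(list(logical(n)), length(.asv_flag_names)), .asv_flag_names)
    )
  }
  x <- structure(
    list(marker = marker, counts = counts,
         taxonomy = as.data.frame(taxonomy, stringsAsFactors = FALSE),
         flags = as.data.frame(flags)),
    class = "asv_table"
  )
  validate_asv_table(x)
}

#' Validate an ASV table against its invariants
#'
#' Checks non-negative integer counts, unique ASV identifiers, strictly
#' increasing integer timepoint labels, a complete taxonomy record per ASV and
#' well-formed flags. Called by every constructor and reader; exposed so that
#' externally assembled objects can be checked too.
#'
#' @param x An `asv_table`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error describing
#'   the first violated invariant.
#' @export
validate_asv_table <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  if (!is.character(x$marker) || length(x$marker) != 1L ||
      !x$marker %in% c("16S", "18S")) {
    stop("marker must be \"16S\" or \"18S\"", call. = FALSE)
  }
  counts <- x$counts
  if (nrow(counts) > 0L &&
      (is.null(rownames(counts)) || anyNA(rownames(counts)))) {
    stop("counts must have ASV identifiers as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicated ASV id: ", dup, call. = FALSE)
  }
  if (anyNA(counts)) stop("counts may not contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at ASV '%s', timepoint %s",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (any(counts != floor(counts))) {
    stop("counts must be whole numbers", call. = FALSE)
  }
  tp <- suppressWarnings(as.integer(colnames(counts)))
  if (anyNA(tp)) {
    stop("timepoint labels must be integer Julian days", call. = FALSE)
  }
  if (ncol(counts) > 1L && any(diff(tp) <= 0L)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (nrow(x$taxonomy) != nrow(counts)) {
    stop("taxonomy must have one row per ASV", call. = FALSE)
  }
  if (!all(tax_ranks() %in% names(x$taxonomy))) {
    stop("taxonomy must contain columns: ",
         paste(tax_ranks(), collapse = ", "), call. = FALSE)
  }
  if (nrow(x$flags) != nrow(counts) ||
      !all(.asv_flag_names %in% names(x$flags)) ||
      !all(vapply(x$flags[.asv_flag_names], is.logical, logical(1L)))) {
    stop("flags must be logical columns ",
         paste(.asv_flag_names, collapse = ", "), " with one row per ASV",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %s marker: %d ASVs x %d timepoints (days %s-%s)\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              colnames(x$counts)[1L], colnames(x$counts)[ncol(x$counts)]))
  cat(sprintf("  flags: %d organelle, %d metazoan, %d benthic\n",
              sum(x$flags$is_organelle), sum(x$flags$is_metazoan),
              sum(x$flags$is_benthic)))
  invisible(x)
}

#' Timepoints of a table
#'
#' @param x An `asv_table` or `env_table`.
#' @return Integer vector of Julian day labels.
#' @export
timepoints <- function(x) {
  if (inherits(x, "asv_table")) return(as.integer(colnames(x$counts)))
  if (inherits(x, "env_table")) return(as.integer(x$timepoint))
  stop("no timepoints for class ", paste(class(x), collapse = "/"))
}

#' Subset an ASV table to a set of rows
#'
#' Keeps counts, taxonomy and flags in register. Used by all filters.
#'
#' @param x An `asv_table`.
#' @param keep Logical or integer index over ASVs.
#' @return The subsetted `asv_table`.
#' @export
subset_asvs <- function(x, keep) {
  stopifnot(inherits(x, "asv_table"))
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$taxonomy <- x$taxonomy[keep, , drop = FALSE]
  out$flags <- x$flags[keep, , drop = FALSE]
  rownames(out$taxonomy) <- NULL
  rownames(out$flags) <- NULL
  validate_asv_table(out)
  out
}

#' Derive exclusion and benthic flags from taxonomy
#'
#' Flags ASVs as organelle-derived (chloroplast or mitochondrial 16S reads),
#' metazoan (18S zooplankton reads) or primarily benthic (diatom genera known
#' from the local benthos). The benthic genus list is configurable rather than
#' hard-coded; the default covers `Nitzschia`, `Navicula` and `Cocconeis`.
#'
#' @param x An `asv_table`.
#' @param benthic_genera Character vector of genus names to flag as benthic.
#' @return `x` with its `flags` columns recomputed from taxonomy (flags
#'   already set on input are kept via logical OR).
#' @export
derive_flags <- function(x, benthic_genera = c("Nitzschia", "Navicula", "Cocconeis")) {
  stopifnot(inherits(x, "asv_table"))
  tax <- x$taxonomy
  organelle <- apply(tax, 1L, function(row) {
    any(grepl("chloroplast|mitochondri", row, ignore.case = TRUE))
  })
  metazoan <- apply(tax, 1L, function(row) {
    any(grepl("^metazoa$", row, ignore.case = TRUE))
  })
  benthic <- tax$genus %in% benthic_genera
  x$flags$is_organelle <- x$flags$is_organelle | organelle
  x$flags$is_metazoan <- x$flags$is_metazoan | metazoan
  x$flags$is_benthic <- x$flags$is_benthic | benthic
  x
}
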