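#' Construct a protein group table
#'
#' Holds metaproteome quantification input: exclusive unique spectrum counts
#' per protein group and sample, the amino-acid length of the longest protein
#' in each group (the length used for spectral abundance factors), a lineage
#' at phylum-level comparability, a function category label and the number of
#' matched peptides per group.
#'
#' @param counts Non-negative integer matrix, groups x samples. Row names are
#'   group ids; column names are sample labels (e.g. `d107_r1` for Julian day
#'   107, replicate 1).
#' @param longest_length Positive integer vector, amino acids, one per group.
#' @param taxonomy Data frame with character columns `domain` and `phylum`,
#'   one row per group.
#' @param function_category Character vector, one per group (COG-like category
#'   or pathway tag such as `"dissimilatory sulfate reduction"`).
#' @param n_peptides Integer vector of matched peptides per group; groups are
#'   only treated as validly detected with at least two (see
#'   [valid_detection_filter()]).
#' @param protein_prob,peptide_prob Optional numeric identification
#'   probabilities in `[0,1]` per group; `NULL` when unavailable.
#' @return An object of class `protein_group_table`.
#' @export
protein_group_table <- function(counts, longest_length, taxonomy,
                                function_category, n_peptides,
                                protein_prob = NULL, peptide_prob = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  x <- structure(
    list(counts = counts,
         longest_length = as.numeric(longest_length),
         taxonomy = as.data.frame(taxonomy, stringsAsFactors = FALSE),
         function_category = as.character(function_category),
         n_peptides = as.integer(n_peptides),
         protein_prob = if (is.null(protein_prob)) NULL else as.numeric(protein_prob),
         peptide_prob = if (is.null(peptide_prob)) NULL else as.numeric(peptide_prob)),
    class = "protein_group_table"
  )
  validate_protein_group_table(x)
}

#' Validate a protein group table
#'
#' @param x A `protein_group_table`.
#' @return `x` if valid, else an error locating the violation.
#' @export
validate_protein_group_table <- function(x) {
  stopifnot(inherits(x, "protein_group_table"))
  n <- nrow(x$counts)
  if (is.null(rownames(x$counts)) || anyDuplicated(rownames(x$counts))) {
    stop("group ids must be unique row names of counts", call. = FALSE)
  }
  if (anyNA(x$counts) || any(x$counts < 0) || any(x$counts != floor(x$counts))) {
    stop("spectrum counts must be non-negative integers", call. = FALSE)
  }
  if (length(x$longest_length) != n || anyNA(x$longest_length) ||
      any(x$longest_length < 1)) {
    bad <- rownames(x$counts)[which(is.na(x$longest_length) | x$longest_length < 1)[1L]]
    stop("longest_length must be >= 1 for every group (group '", bad, "')",
         call. = FALSE)
  }
  if (nrow(x$taxonomy) != n || !all(c("domain", "phylum") %in% names(x$taxonomy))) {
    stop("taxonomy must have one row per group with columns domain, phylum",
         call. = FALSE)
  }
  if (length(x$function_category) != n) {
    stop("function_category must have one entry per group", call. = FALSE)
  }
  if (length(x$n_peptides) != n || anyNA(x$n_peptides) || any(x$n_peptides < 0)) {
    stop("n_peptides must be a non-negative integer per group", call. = FALSE)
  }
  for (p in c("protein_prob", "peptide_prob")) {
    if (!is.null(x[[p]]) &&
        (length(x[[p]]) != n || any(x[[p]] < 0 | x[[p]] > 1, na.rm = TRUE))) {
      stop(p, " must be one probability in [0,1] per group", call. = FALSE)
    }
  }
  x
}

#' @export
print.protein_group_table <- function(x, ...) {
  cat(sprintf("<protein_group_table> %d groups x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
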