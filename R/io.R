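#' Read an ASV count table from TSV
#'
#' Expected layout: an `asv_id` column, one count column per timepoint whose
#' header is the integer Julian day label, the taxonomy rank columns of
#' [tax_ranks()], and optionally the flag columns `is_organelle`,
#' `is_metazoan`, `is_benthic`. Any other column is rejected. Tables are
#' validated on read: malformed numeric cells, duplicated ids and
#' non-monotone timepoints raise located errors rather than being coerced.
#'
#' @param path Path to a tab-separated UTF-8 file with '.' decimals.
#' @param marker `"16S"` or `"18S"`, the marker the table belongs to.
#' @return A validated [asv_table()].
#' @export
read_asv_table <- function(path, marker) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (!"asv_id" %in% names(raw)) stop("missing 'asv_id' column in ", path)
  count_cols <- names(raw)[grepl("^[0-9]+$", names(raw))]
  if (length(count_cols) == 0L) stop("no timepoint count columns found in ", path)
  known <- c("asv_id", count_cols, tax_ranks(), .asv_flag_names)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  counts <- matrix(NA_real_, nrow = nrow(raw), ncol = length(count_cols),
                   dimnames = list(raw$asv_id, count_cols))
  for (j in count_cols) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad) > 0L) {
      stop(sprintf("malformed count '%s' at row '%s', column '%s' in %s",
                   raw[[j]][bad[1L]], raw$asv_id[bad[1L]], j, path))
    }
    counts[, j] <- v
  }
  taxonomy <- as.data.frame(
    setNames(lapply(tax_ranks(), function(r) {
      if (r %in% names(raw)) raw[[r]] else rep("", nrow(raw))
    }), tax_ranks()),
    stringsAsFactors = FALSE
  )
  flags <- as.data.frame(
    setNames(lapply(.asv_flag_names, function(f) {
      if (f %in% names(raw)) toupper(raw[[f]]) %in% c("TRUE", "T", "1")
      else rep(FALSE, nrow(raw))
    }), .asv_flag_names)
  )
  asv_table(counts, marker = marker, taxonomy = taxonomy, flags = flags)
}

#' Write an ASV count table to TSV
#'
#' Inverse of [read_asv_table()]; `read_asv_table(write_asv_table(x))` is the
#' identity on counts, taxonomy and flags.
#'
#' @param x An `asv_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path) {
  validate_asv_table(x)
  df <- data.frame(asv_id = rownames(x$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in colnames(x$counts)) df[[j]] <- as.integer(x$counts[, j])
  for (r in tax_ranks()) df[[r]] <- x$taxonomy[[r]]
  for (f in .asv_flag_names) df[[f]] <- x$flags[[f]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an environmental covariate table from TSV
#'
#' Missing values are encoded as the literal `NA`.
#'
#' @param path Path to a TSV with the columns of [env_table()].
#' @return A validated `env_table`.
#' @export
read_env_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.env_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("env table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  td <- raw$tide_direction
  td[is.na(td)] <- "unknown"
  env_table(timepoint = raw$timepoint, chl_a = raw$chl_a,
            secchi_depth = raw$secchi_depth,
            wind_speed_max = raw$wind_speed_max,
            water_level = raw$water_level,
            detritus_score = raw$detritus_score,
            tide_direction = td)
}

#' Write an environmental covariate table to TSV
#'
#' @param x An `env_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(x, path) {
  validate_env_table(x)
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.pg_fixed_cols <- c("group_id", "longest_length", "n_peptides", "domain",
                    "phylum", "function_category", "protein_prob",
                    "peptide_prob")

#' Read a protein group table from TSV
#'
#' Expected layout: `group_id`, one spectrum-count column per sample (any
#' header not in the fixed metadata set is treated as a sample), and the
#' metadata columns `longest_length`, `n_peptides`, `domain`, `phylum`,
#' `function_category` plus optional `protein_prob` / `peptide_prob`.
#'
#' @param path Path to a TSV file.
#' @return A validated [protein_group_table()].
#' @export
read_protein_groups <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                           stringsAsFactors = FALSE)
  need <- c("group_id", "longest_length", "n_peptides", "domain", "phylum",
            "function_category")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("protein group table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(raw), .pg_fixed_cols)
  if (length(sample_cols) == 0L) stop("no sample columns found in ", path)
  counts <- as.matrix(raw[, sample_cols, drop = FALSE])
  rownames(counts) <- raw$group_id
  protein_group_table(
    counts = counts,
    longest_length = raw$longest_length,
    taxonomy = raw[, c("domain", "phylum")],
    function_category = raw$function_category,
    n_peptides = raw$n_peptides,
    protein_prob = if ("protein_prob" %in% names(raw)) raw$protein_prob else NULL,
    peptide_prob = if ("peptide_prob" %in% names(raw)) raw$peptide_prob else NULL
  )
}

#' Write a protein group table to TSV
#'
#' @param x A `protein_group_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) {
  validate_protein_group_table(x)
  df <- data.frame(group_id = rownames(x$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in colnames(x$counts)) df[[j]] <- as.integer(x$counts[, j])
  df$longest_length <- as.integer(x$longest_length)
  df$n_peptides <- x$n_peptides
  df$domain <- x$taxonomy$domain
  df$phylum <- x$taxonomy$phylum
  df$function_category <- x$function_category
  if (!is.null(x$protein_prob)) df$protein_prob <- x$protein_prob
  if (!is.null(x$peptide_prob)) df$peptide_prob <- x$peptide_prob
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Persist a co-occurrence network
#'
#' GraphML output (via igraph) preserves node attributes `domain`,
#' `taxonomy`, `degree`, `module_id` and edge attributes `rho`, `p_raw`,
#' `p_adj` and is loadable by standard graph tools; `edge_tsv` writes one
#' edge per line with columns `node_a` (18S), `node_b` (16S), `rho`, `p_raw`,
#' `p_adj`. Unassigned modules are stored as id 0 in GraphML.
#'
#' @param net A `co_network` (see [build_network()]).
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "co_network"))
  if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  nodes <- net$nodes
  nodes$module_id[is.na(nodes$module_id)] <- 0L
  g <- igraph::graph_from_data_frame(
    d = net$edges[, c("node_a", "node_b", "rho", "p_raw", "p_adj")],
    directed = FALSE,
    vertices = data.frame(name = nodes$id, domain = nodes$domain,
                          taxonomy = nodes$taxonomy, degree = nodes$degree,
                          module_id = nodes$module_id,
                          stringsAsFactors = FALSE)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a co-occurrence network back from disk
#'
#' Reconstructs the node and edge tables from a GraphML or edge-list TSV file
#' written by [write_network()]. Edge-list TSV carries no node metadata, so
#' nodes are rebuilt with degree only.
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return A `co_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- utils::read.delim(path, check.names = FALSE,
                               stringsAsFactors = FALSE)
    edges$node_a <- as.character(edges$node_a)
    edges$node_b <- as.character(edges$node_b)
    ids <- unique(c(edges$node_a, edges$node_b))
    deg <- vapply(ids, function(i) sum(edges$node_a == i) + sum(edges$node_b == i),
                  integer(1L))
    nodes <- data.frame(id = ids,
                        domain = ifelse(ids %in% edges$node_a, "18S", "16S"),
                        taxonomy = "", degree = deg, module_id = NA_integer_,
                        stringsAsFactors = FALSE)
    return(new_co_network(nodes, edges, params = list()))
  }
  g <- igraph::read_graph(path, format = "graphml")
  vnames <- igraph::vertex_attr(g, "name")
  nodes <- data.frame(
    id = vnames,
    domain = igraph::vertex_attr(g, "domain"),
    taxonomy = igraph::vertex_attr(g, "taxonomy"),
    degree = as.integer(igraph::vertex_attr(g, "degree")),
    module_id = as.integer(igraph::vertex_attr(g, "module_id")),
    stringsAsFactors = FALSE
  )
  nodes$module_id[nodes$module_id == 0L] <- NA_integer_
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(
    node_a = if (nrow(el) > 0L) el[, 1L] else character(0L),
    node_b = if (nrow(el) > 0L) el[, 2L] else character(0L),
    rho = igraph::edge_attr(g, "rho") %||% numeric(0L),
    p_raw = igraph::edge_attr(g, "p_raw") %||% numeric(0L),
    p_adj = igraph::edge_attr(g, "p_adj") %||% numeric(0L),
    stringsAsFactors = FALSE
  )
  # graphml edge order does not encode which endpoint was the 18S node;
  # restore orientation from the node domains
  if (nrow(edges) > 0L) {
    dom <- setNames(nodes$domain, nodes$id)
    flip <- dom[edges$node_a] == "16S"
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
  }
  new_co_network(nodes, edges, params = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
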