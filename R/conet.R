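#' Internal co_network constructor
#'
#' @param nodes Data frame with columns `id`, `domain` (`"16S"`/`"18S"`),
#'   `taxonomy` (semicolon-joined lineage, ranks in [tax_ranks()] order),
#'   `degree`, `module_id`.
#' @param edges Data frame with columns `node_a` (18S id), `node_b` (16S id),
#'   `rho`, `p_raw`, `p_adj`.
#' @param params List of the thresholds that produced the network.
#' @return A `co_network` object.
#' @keywords internal
new_co_network <- function(nodes, edges, params) {
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("<co_network> %d nodes (%d x 18S, %d x 16S), %d edges\n",
              nrow(x$nodes), sum(x$nodes$domain == "18S"),
              sum(x$nodes$domain == "16S"), nrow(x$edges)))
  if (!is.null(x$params$rho_min)) {
    cat(sprintf("  edge rule: rho > %g and BH-adjusted p < %g (pool: %s)\n",
                x$params$rho_min, x$params$alpha, x$params$adjust_pool))
  }
  k <- x$nodes$module_id
  if (length(k) > 0L && !all(is.na(k))) {
    cat(sprintf("  modules: %d (largest %d nodes)\n", max(k, na.rm = TRUE),
                max(tabulate(k))))
  }
  invisible(x)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks (ties
#' receive the mean of the ranks they span) and a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, the approximation used by common rank-correlation
#' implementations at the series lengths of a bloom time series (n around
#' 50). `rho = +/-1` yields `p_raw = 0` by convention.
#'
#' A constant series has no rank variation, so rho is undefined there; the
#' function returns `NA` for rho and p together with `constant = TRUE`, which
#' downstream edge selection treats as "no edge" (never as a propagating
#' NaN).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p_raw`, `n` and the logical `constant`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("series may not contain missing values")
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_raw = NA_real_, n = n, constant = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  list(rho = rho, p_raw = .spearman_p(rho, n), n = n, constant = FALSE)
}

# two-sided p from the t approximation; exactly monotone rho -> p = 0
.spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  exact <- abs(rho) >= 1
  p[exact] <- 0
  tt <- rho[!exact] * sqrt((n - 2) / (1 - rho[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: p-values are sorted ascending,
#' `q_(i) = p_(i) * m / i`, monotonicity is enforced by a cumulative minimum
#' from the largest index down, values are capped at 1 and returned in the
#' original order. Agrees with `stats::p.adjust(method = "BH")` to floating
#' precision (the two differ only in the association order of the
#' multiplication).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0L))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Build the cross-kingdom co-occurrence network
#'
#' Computes pairwise Spearman correlations, applies Benjamini-Hochberg
#' adjustment over the chosen pool, and emits an edge for every 18S-16S pair
#' with `rho > rho_min` and adjusted `p < alpha` (both strict; `rho_min > 0`
#' restricts the network to significant positive correlations). Node degree
#' is the incident edge count and nodes with degree 0 are omitted.
#'
#' The conventional procedure correlates *all* remaining ASV pairs, adjusts
#' over that pool, and only then restricts to cross-domain pairs
#' (`adjust_pool = "all_pairs"`, the default). The statistically tighter
#' alternative adjusts only over the cross-domain pairs that can become edges
#' (`"cross_domain_only"`). Constant series are dropped from the pool and
#' counted in `params$n_constant_dropped`.
#'
#' @param euk 18S abundance input: an `asv_table` (converted to relative
#'   abundance) or a numeric ASV x timepoint matrix, already filtered.
#' @param bac 16S counterpart of `euk`.
#' @param rho_min Positive edge threshold on rho (strict `>`), default 0.7.
#' @param alpha Threshold on the BH-adjusted p-value (strict `<`),
#'   default 0.01.
#' @param adjust_pool `"all_pairs"` or `"cross_domain_only"`.
#' @param use_relative Convert `asv_table` counts to relative abundances
#'   before correlating (default `TRUE`; Spearman is not invariant to
#'   per-sample closure when library sizes differ, so the choice is exposed).
#' @return A `co_network`; `$records` holds every computed cross-domain
#'   correlation (including negative and non-significant ones) as a
#'   data frame of correlation records.
#' @export
build_network <- function(euk, bac, rho_min = 0.7, alpha = 0.01,
                          adjust_pool = c("all_pairs", "cross_domain_only"),
                          use_relative = TRUE) {
  adjust_pool <- match.arg(adjust_pool)
  if (rho_min <= 0) stop("rho_min must be positive (positive co-occurrence only)")
  euk_tax <- .node_taxonomy(euk)
  bac_tax <- .node_taxonomy(bac)
  A_euk <- .abundance_matrix(euk, use_relative)
  A_bac <- .abundance_matrix(bac, use_relative)
  if (!identical(colnames(A_euk), colnames(A_bac))) {
    stop("euk and bac tables must share an identical timepoint set")
  }
  n <- ncol(A_euk)
  if (n < 4L) stop("need at least 4 shared timepoints")
  if (anyDuplicated(c(rownames(A_euk), rownames(A_bac)))) {
    stop("ASV ids must be unique across the two tables")
  }

  # rank each ASV's series; constant series carry no rank signal and are
  # excluded from both the pool and the edge candidates
  rank_rows <- function(A) t(apply(A, 1L, rank))
  const_e <- apply(A_euk, 1L, function(v) sd(v) == 0)
  const_b <- apply(A_bac, 1L, function(v) sd(v) == 0)
  Re_ <- rank_rows(A_euk[!const_e, , drop = FALSE])
  Rb_ <- rank_rows(A_bac[!const_b, , drop = FALSE])
  ne <- nrow(Re_); nb <- nrow(Rb_)

  cross <- if (ne > 0L && nb > 0L) stats::cor(t(Re_), t(Rb_)) else
    matrix(numeric(0L), ne, nb)
  cross[] <- pmax(-1, pmin(1, cross))
  p_cross <- matrix(.spearman_p(as.vector(cross), n), ne, nb,
                    dimnames = dimnames(cross))

  if (adjust_pool == "all_pairs") {
    # pool = all unordered pairs among the non-constant ASVs of both domains
    R_all <- rbind(Re_, Rb_)
    C_all <- stats::cor(t(R_all))
    C_all[] <- pmax(-1, pmin(1, C_all))
    ut <- upper.tri(C_all)
    pool_p <- .spearman_p(C_all[ut], n)
    pool_adj <- bh_adjust(pool_p)
    M_adj <- matrix(NA_real_, nrow(C_all), ncol(C_all),
                    dimnames = dimnames(C_all))
    M_adj[ut] <- pool_adj
    M_adj[lower.tri(M_adj)] <- t(M_adj)[lower.tri(M_adj)]
    p_adj <- M_adj[seq_len(ne), ne + seq_len(nb), drop = FALSE]
  } else {
    p_adj <- matrix(bh_adjust(as.vector(p_cross)), ne, nb,
                    dimnames = dimnames(p_cross))
  }

  records <- data.frame(
    id_18s = rep(rownames(cross), times = nb),
    id_16s = rep(colnames(cross), each = ne),
    rho = as.vector(cross),
    p_raw = as.vector(p_cross),
    p_adj = as.vector(p_adj),
    n = n,
    stringsAsFactors = FALSE
  )
  hit <- records$rho > rho_min & records$p_adj < alpha
  edges <- data.frame(node_a = records$id_18s[hit],
                      node_b = records$id_16s[hit],
                      rho = records$rho[hit],
                      p_raw = records$p_raw[hit],
                      p_adj = records$p_adj[hit],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- c(sort(unique(edges$node_a)), sort(unique(edges$node_b)))
  deg <- vapply(ids, function(i) {
    sum(edges$node_a == i) + sum(edges$node_b == i)
  }, integer(1L))
  tax <- c(euk_tax, bac_tax)
  nodes <- data.frame(
    id = ids,
    domain = as.character(ifelse(ids %in% edges$node_a, "18S", "16S")),
    taxonomy = as.character(unname(tax[ids])),
    degree = as.integer(deg),
    module_id = rep(NA_integer_, length(ids)),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  net <- new_co_network(nodes, edges, params = list(
    rho_min = rho_min, alpha = alpha, adjust_pool = adjust_pool,
    n_timepoints = n,
    n_constant_dropped = sum(const_e) + sum(const_b)
  ))
  net$records <- records
  net
}

.abundance_matrix <- function(x, use_relative) {
  if (inherits(x, "asv_table")) {
    if (use_relative) relative_abundance(x) else x$counts
  } else {
    as.matrix(x)
  }
}

.node_taxonomy <- function(x) {
  if (inherits(x, "asv_table")) {
    setNames(apply(x$taxonomy[tax_ranks()], 1L, paste, collapse = ";"),
             rownames(x$counts))
  } else {
    setNames(rep(paste(rep("", length(tax_ranks())), collapse = ";"),
                 nrow(x)), rownames(x))
  }
}

#' Assign network modules
#'
#' The default detection is connected components of the thresholded bipartite
#' graph: deterministic, parameter-free, and exactly the notion of "distinct
#' modules" that separated bloom pulses produce. Louvain modularity
#' optimisation is available for dense networks where components merge.
#' Module ids are `1..k` ordered by descending node count (ties broken by the
#' lexicographically smallest member id); singleton components are allowed.
#'
#' @param net A `co_network`.
#' @param method `"components"` (default) or `"louvain"`.
#' @return `net` with `nodes$module_id` populated.
#' @export
extract_modules <- function(net, method = c("components", "louvain")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$nodes) == 0L) return(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = net$nodes$id
  )
  raw <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    igraph::membership(igraph::cluster_louvain(g))
  }
  raw <- raw[net$nodes$id]
  # relabel 1..k by descending size, ties by smallest member id
  sizes <- table(raw)
  first_id <- vapply(names(sizes), function(m) {
    min(net$nodes$id[raw == as.integer(m)])
  }, character(1L))
  ord <- order(-as.integer(sizes), first_id)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  net$nodes$module_id <- as.integer(relabel[as.character(raw)])
  net$params$module_method <- method
  net
}

#' Per-module lineage composition
#'
#' For each module and domain, counts member ASVs per lineage at the chosen
#' rank (the bar-plot summary of which bacterial lineages co-occur with which
#' eukaryote bloom). Additionally reports, per (domain, lineage), the set of
#' modules it appears in: a lineage is module-exclusive iff it occurs in
#' exactly one module, supporting statements of the form "lineage X
#' co-occurred exclusively with module-I eukaryotes".
#'
#' @param net A `co_network` with modules assigned.
#' @param rank One of [tax_ranks()].
#' @return A list with `composition` (data frame: `module_id`, `domain`,
#'   `lineage`, `n_asv`) and `exclusivity` (data frame: `domain`, `lineage`,
#'   `modules` (comma-joined), `exclusive`).
#' @export
module_composition <- function(net, rank = "phylum") {
  stopifnot(inherits(net, "co_network"), rank %in% tax_ranks())
  nodes <- net$nodes
  if (nrow(nodes) == 0L) {
    return(list(
      composition = data.frame(module_id = integer(0L), domain = character(0L),
                               lineage = character(0L), n_asv = integer(0L)),
      exclusivity = data.frame(domain = character(0L), lineage = character(0L),
                               modules = character(0L), exclusive = logical(0L))
    ))
  }
  if (all(is.na(nodes$module_id))) stop("modules not assigned; run extract_modules()")
  lineage <- lineage_at_rank(nodes$taxonomy, rank)
  key <- paste(nodes$module_id, nodes$domain, lineage, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  composition <- data.frame(
    module_id = as.integer(parts[, 1L]),
    domain = parts[, 2L],
    lineage = parts[, 3L],
    n_asv = as.integer(tab),
    stringsAsFactors = FALSE
  )
  composition <- composition[order(composition$module_id, composition$domain,
                                   -composition$n_asv, composition$lineage), ]
  rownames(composition) <- NULL
  dl <- unique(data.frame(domain = nodes$domain, lineage = lineage,
                          stringsAsFactors = FALSE))
  mods <- mapply(function(d, l) {
    sort(unique(nodes$module_id[nodes$domain == d & lineage == l]))
  }, dl$domain, dl$lineage, SIMPLIFY = FALSE)
  exclusivity <- data.frame(
    domain = dl$domain,
    lineage = dl$lineage,
    modules = vapply(mods, paste, character(1L), collapse = ","),
    exclusive = vapply(mods, length, integer(1L)) == 1L,
    stringsAsFactors = FALSE
  )
  rownames(exclusivity) <- NULL
  list(composition = composition, exclusivity = exclusivity)
}

#' Extract one rank from a semicolon-joined lineage string
#'
#' @param lineage Character vector of `;`-joined lineages in [tax_ranks()]
#'   order.
#' @param rank One of [tax_ranks()].
#' @return Character vector of the names at that rank (may be `""`).
#' @export
lineage_at_rank <- function(lineage, rank) {
  i <- match(rank, tax_ranks())
  if (is.na(i)) stop("unknown rank: ", rank)
  vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    if (length(parts) >= i) parts[i] else ""
  }, character(1L))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; used
#' to score recovery of planted module membership. 1 means identical
#' partitions (up to label permutation), 0 the expectation under random
#' labeling.
#'
#' @param a,b Vectors of labels of equal length.
#' @return The adjusted Rand index, a single number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must label the same items")
  n <- length(a)
  if (n == 0L) return(1)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
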