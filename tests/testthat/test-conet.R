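test_that("spearman_rho handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$p_raw, 0)
  expect_equal(spearman_rho(1:4, 4:1)$rho, -1)

  tied <- spearman_rho(c(1, 2, 2, 4), c(3, 1, 2, 4))
  orac <- oracle_spearman(c(1, 2, 2, 4), c(3, 1, 2, 4))
  expect_equal(tied$rho, orac$rho, tolerance = 1e-12)
  expect_equal(tied$p_raw, orac$p, tolerance = 1e-12)

  const <- spearman_rho(rep(2, 5), 1:5)
  expect_true(const$constant)
  expect_true(is.na(const$rho))

  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  expect_error(spearman_rho(1:5, 1:4), "equal length")
})

test_that("spearman_rho is symmetric and invariant to monotone transforms", {
  set.seed(41)
  for (i in 1:20) {
    x <- sample(1:20, 15, replace = TRUE)   # ties likely
    y <- rnorm(15)
    a <- spearman_rho(x, y)
    expect_equal(a$rho, spearman_rho(y, x)$rho, tolerance = 1e-12)
    expect_equal(a$rho, spearman_rho(exp(x / 5), y^3 + 2 * y)$rho,
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand-computed step-up cases and validates input", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04), tolerance = 1e-15)
  expect_equal(bh_adjust(c(0.01, 0.01, 0.01)), c(0.01, 0.01, 0.01))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(42)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(q, oracle_bh(p))
  # independent reference implementation
  expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
})

test_that("a shared monotone series across domains yields exactly one edge", {
  days <- as.character(seq(60, by = 1, length.out = 51))
  base <- seq_len(51)
  euk <- matrix(base, 1L, dimnames = list("e1", days))
  bac <- matrix(base^2, 1L, dimnames = list("b1", days))
  net <- build_network(euk, bac)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$node_a, "e1")
  expect_identical(net$edges$node_b, "b1")
  expect_equal(net$nodes$degree, c(1L, 1L))
  expect_equal(net$edges$rho, 1)
})

test_that("rho exactly at the threshold produces no edge (strict inequality)", {
  # ranks (1,2,5,3,4) against (1..5): sum of squared rank differences 6,
  # so rho = 1 - 6*6/(5*24) = 0.7 exactly
  days <- as.character(61:65)
  euk <- matrix(1:5, 1L, dimnames = list("e1", days))
  bac <- matrix(c(1, 2, 5, 3, 4), 1L, dimnames = list("b1", days))
  expect_equal(spearman_rho(1:5, c(1, 2, 5, 3, 4))$rho, 0.7)
  net <- build_network(euk, bac, rho_min = 0.7, alpha = 1)
  expect_identical(nrow(net$edges), 0L)
})

test_that("constant series are dropped, never NaN-propagated", {
  days <- as.character(seq(60, length.out = 10))
  euk <- matrix(c(1:10, rep(3, 10)), 2L, byrow = TRUE,
                dimnames = list(c("e1", "e2"), days))
  bac <- matrix(c(1:10, rep(5, 10)), 2L, byrow = TRUE,
                dimnames = list(c("b1", "b2"), days))
  net <- build_network(euk, bac, alpha = 0.05)
  expect_identical(net$params$n_constant_dropped, 2L)
  expect_false(any(is.na(net$edges$rho)))
  expect_false(any(c("e2", "b2") %in% net$nodes$id))
})

test_that("build_network validates timepoints and is invariant to row order", {
  days <- as.character(seq(60, length.out = 12))
  set.seed(43)
  euk <- matrix(rnorm(5 * 12), 5L, dimnames = list(paste0("e", 1:5), days))
  bac <- matrix(rnorm(8 * 12), 8L, dimnames = list(paste0("b", 1:8), days))
  expect_error(build_network(euk, bac[, 1:11]), "timepoint")
  expect_error(build_network(euk[, 1:3], bac[, 1:3]), "at least 4")

  n1 <- build_network(euk, bac, rho_min = 0.3, alpha = 0.5)
  n2 <- build_network(euk[sample(5), ], bac[sample(8), ],
                      rho_min = 0.3, alpha = 0.5)
  key <- function(n) sort(paste(n$edges$node_a, n$edges$node_b, sep = "|"))
  expect_identical(key(n1), key(n2))

  # threshold monotonicity: stricter rho_min yields an edge subset
  loose <- build_network(euk, bac, rho_min = 0.3, alpha = 0.5)
  tight <- build_network(euk, bac, rho_min = 0.9, alpha = 0.5)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("edges match the brute-force oracle under both adjustment pools", {
  cfg <- sim_config(seed = 17, n_background_16s = 12L, n_background_18s = 6L)
  sim <- simulate_bloom(cfg)
  f16 <- filter_rare(remove_excluded_taxa(sim$asv_16s), 100)
  f18 <- filter_rare(remove_excluded_taxa(sim$asv_18s), 500)
  A_euk <- relative_abundance(f18)
  A_bac <- relative_abundance(f16)
  for (pool in c("all_pairs", "cross_domain_only")) {
    net <- build_network(f18, f16, adjust_pool = pool)
    got <- sort(paste(net$edges$node_a, net$edges$node_b, sep = "|"))
    want <- oracle_network_edges(A_euk, A_bac, 0.7, 0.01, pool)
    expect_identical(got, want)
  }
})

test_that("modules are connected components ordered by size", {
  # two disjoint planted cliques of sizes 10 (5 euk x 5 bac) and 6 (3 x 3):
  # every cross pair within a clique is an edge
  days <- as.character(seq(60, length.out = 20))
  s1 <- seq_len(20) + 0.0
  s2 <- 20 - s1 * 1.5
  mk <- function(ids, series, jitter) {
    m <- do.call(rbind, lapply(seq_along(ids), function(i) {
      rank(series) + jitter * i * 1e-9
    }))
    rownames(m) <- ids
    colnames(m) <- days
    m
  }
  euk <- rbind(mk(paste0("e1_", 1:5), s1, 0), mk(paste0("e2_", 1:3), s2, 0))
  bac <- rbind(mk(paste0("b1_", 1:5), s1, 0), mk(paste0("b2_", 1:3), s2, 0))
  net <- extract_modules(build_network(euk, bac))
  sizes <- as.integer(table(net$nodes$module_id))
  expect_identical(sizes, c(10L, 6L))
  expect_identical(sort(unique(net$nodes$module_id)), c(1L, 2L))
  m1 <- net$nodes$id[net$nodes$module_id == 1L]
  expect_setequal(m1, c(paste0("e1_", 1:5), paste0("b1_", 1:5)))

  # path graph stays one module
  nodes <- data.frame(id = c("a", "b", "c"), domain = c("18S", "16S", "18S"),
                      taxonomy = ";;;;;", degree = c(1L, 2L, 1L),
                      module_id = NA_integer_, stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("a", "c"), node_b = c("b", "b"),
                      rho = 0.9, p_raw = 0, p_adj = 0,
                      stringsAsFactors = FALSE)
  path_net <- extract_modules(bloomnet:::new_co_network(nodes, edges, list()))
  expect_identical(unique(path_net$nodes$module_id), 1L)

  # empty network -> empty assignment
  empty <- extract_modules(bloomnet:::new_co_network(nodes[0L, ], edges[0L, ],
                                                     list()))
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("module composition counts lineages and flags exclusivity", {
  nodes <- data.frame(
    id = c(paste0("d", 1:11), "e1", "x1", "x2"),
    domain = c(rep("16S", 11), "18S", "16S", "16S"),
    taxonomy = c(rep("Bacteria;Desulfobacterota;;;;", 11),
                 "Eukaryota;Bacillariophyta;;;;",
                 rep("Bacteria;Proteobacteria;;;;", 2)),
    degree = 1L,
    module_id = c(rep(1L, 12), 1L, 2L),
    stringsAsFactors = FALSE)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      rho = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0))
  net <- bloomnet:::new_co_network(nodes, edges, list())
  comp <- module_composition(net, "phylum")
  desulfo <- comp$composition[comp$composition$lineage == "Desulfobacterota", ]
  expect_identical(desulfo$n_asv, 11L)
  expect_identical(desulfo$module_id, 1L)
  exc <- comp$exclusivity
  expect_true(exc$exclusive[exc$lineage == "Desulfobacterota"])
  expect_false(exc$exclusive[exc$lineage == "Proteobacteria"])
  expect_identical(exc$modules[exc$lineage == "Proteobacteria"], "1,2")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 2, 3)), 0)
  set.seed(44)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
})
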