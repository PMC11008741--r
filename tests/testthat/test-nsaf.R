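make_pg <- function(counts, lengths, phylum = NULL, category = NULL) {
  n <- nrow(counts)
  protein_group_table(
    counts = counts,
    longest_length = lengths,
    taxonomy = data.frame(domain = rep("Bacteria", n),
                          phylum = phylum %||% rep("P", n),
                          stringsAsFactors = FALSE),
    function_category = category %||% rep("misc", n),
    n_peptides = rep(2L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("NSAF follows the length-normalised worked example", {
  counts <- matrix(c(10, 10), 2L, 1L, dimnames = list(c("g1", "g2"), "d107_r1"))
  m <- nsaf(make_pg(counts, c(100, 200)))
  expect_equal(unname(m[, 1L]), c(2 / 3, 1 / 3), tolerance = 1e-15)

  one <- matrix(7, 1L, 1L, dimnames = list("g1", "d107_r1"))
  expect_equal(unname(nsaf(make_pg(one, 431))[1L, 1L]), 1)

  cfg <- sim_config(seed = 13)
  m2 <- nsaf(simulate_metaproteome(cfg))
  expect_true(all(abs(colSums(m2) - 1) < 1e-9))

  zero <- matrix(c(1, 0, 0, 0), 2L, 2L,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(nsaf(make_pg(zero, c(100, 100))), "s2")
})

test_that("NSAF is invariant to uniform length rescaling and reacts to one length", {
  set.seed(51)
  counts <- matrix(rpois(12, 20) + 1, 4L, 3L,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  len <- c(120, 500, 800, 1400)
  m1 <- nsaf(make_pg(counts, len))
  m2 <- nsaf(make_pg(counts, len * 3))
  expect_equal(m1, m2, tolerance = 1e-12)
  # doubling one group's length halves its SAF, decreasing its NSAF while
  # every other group's NSAF rises
  len2 <- len; len2[2L] <- len2[2L] * 2
  m3 <- nsaf(make_pg(counts, len2))
  expect_true(all(m3[2L, ] < m1[2L, ]))
  expect_true(all(m3[-2L, ] > m1[-2L, ]))
})

test_that("taxon shares sum to one over a lineage partition and average correctly", {
  set.seed(52)
  counts <- matrix(rpois(18, 30) + 1, 6L, 3L,
                   dimnames = list(paste0("g", 1:6),
                                   c("d107_r1", "d107_r2", "d128_r1")))
  phy <- c("A", "A", "B", "B", "C", "C")
  pg <- make_pg(counts, rep(300, 6L), phylum = phy)
  m <- nsaf(pg)
  shares <- sapply(c("A", "B", "C"), function(p) taxon_share(m, pg, p))
  expect_equal(unname(rowSums(shares)), rep(1, 3L), tolerance = 1e-12)

  # replicates averaged within timepoint before the grand mean
  sA <- taxon_share(m, pg, "A")
  expect_equal(taxon_share(m, pg, "A", average = "over_all_samples"),
               mean(c(mean(sA[1:2]), sA[3L])), tolerance = 1e-12)
  expect_equal(taxon_share(m, pg, "A", average = "over_all_samples",
                           replicates_first = FALSE),
               mean(sA), tolerance = 1e-12)
  expect_equal(unname(taxon_share(m, pg, "absent")), rep(0, 3L))
})

test_that("within-taxon function fraction mirrors the abundance-weighted ratio", {
  # one sample, equal lengths: NSAF mass proportional to counts.
  # lineage mass 0.10 of which category 0.032 -> fraction 0.32
  counts <- matrix(c(32, 68, 900), 3L, 1L,
                   dimnames = list(paste0("g", 1:3), "d107_r1"))
  pg <- make_pg(counts, rep(250, 3L),
                phylum = c("Desulfobacterota", "Desulfobacterota", "Other"),
                category = c("dissimilatory sulfate reduction", "misc", "misc"))
  m <- nsaf(pg)
  expect_equal(sum(m[1:2, ]), 0.10, tolerance = 1e-12)
  expect_equal(
    within_taxon_function_fraction(m, pg, "Desulfobacterota",
                                   "dissimilatory sulfate reduction"),
    0.32, tolerance = 1e-12)
  # covering category -> 1; absent category -> 0
  expect_equal(within_taxon_function_fraction(m, pg, "Other", "misc"), 1)
  expect_equal(within_taxon_function_fraction(m, pg, "Other", "nope"), 0)
  expect_error(within_taxon_function_fraction(m, pg, "Missing", "misc"),
               "no NSAF mass")
})

test_that("valid detection keeps >= 2 peptides and applies optional probabilities", {
  n <- 25L
  counts <- matrix(1, n, 1L, dimnames = list(sprintf("g%02d", 1:n), "s1"))
  npep <- rep(3L, n); npep[1:6] <- 1L    # 6 below the peptide floor
  pg <- protein_group_table(counts, rep(200, n),
                            data.frame(domain = rep("B", n),
                                       phylum = rep("P", n)),
                            rep("misc", n), npep)
  kept <- valid_detection_filter(pg)
  expect_identical(nrow(kept$counts), 19L)
  expect_identical(attr(kept, "detection_thresholds")$min_peptides, 2L)

  pg2 <- protein_group_table(counts, rep(200, n),
                             data.frame(domain = rep("B", n),
                                        phylum = rep("P", n)),
                             rep("misc", n), rep(2L, n),
                             protein_prob = c(rep(0.999, n - 2L), 0.8, 0.99),
                             peptide_prob = c(0.5, rep(0.96, n - 1L)))
  kept2 <- valid_detection_filter(pg2)
  # one fails protein prob (0.8), one fails peptide prob (0.5); 0.99 on the
  # boundary survives (>= threshold)
  expect_identical(nrow(kept2$counts), n - 2L)
})
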