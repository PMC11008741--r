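test_that("ASV tables round-trip through TSV including taxonomy and flags", {
  x <- random_asv_table(n_asv = 3L, n_tp = 4L, seed = 11)
  x$flags$is_benthic[2L] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(x, path)
  y <- read_asv_table(path, "16S")
  expect_identical(dim(y$counts), c(3L, 4L))
  expect_equal(y$counts, x$counts)
  expect_identical(y$taxonomy, x$taxonomy)
  expect_identical(y$flags, x$flags)
  expect_identical(y$marker, "16S")
})

test_that("malformed ASV tables are rejected with located errors", {
  x <- random_asv_table(n_asv = 3L, n_tp = 4L, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(x, path)

  lines <- readLines(path)
  neg <- sub("^(asv_001\t)\\d+", "\\1-5", lines)
  withr::with_tempfile("f", {
    writeLines(neg, f)
    expect_error(read_asv_table(f, "16S"), "asv_001")
  })

  dup <- c(lines, sub("^asv_003", "asv_001", lines[4L]))
  withr::with_tempfile("f", {
    writeLines(dup, f)
    expect_error(read_asv_table(f, "16S"), "duplicated ASV id")
  })

  hdr <- strsplit(lines[1L], "\t")[[1L]]
  hdr[2:3] <- hdr[3:2]   # swap two timepoint labels -> non-monotone
  withr::with_tempfile("f", {
    writeLines(c(paste(hdr, collapse = "\t"), lines[-1L]), f)
    expect_error(read_asv_table(f, "16S"), "strictly increasing")
  })

  withr::with_tempfile("f", {
    writeLines(paste0(lines, c("\tis_weird", rep("\tTRUE", length(lines) - 1L))), f)
    expect_error(read_asv_table(f, "16S"), "unknown column")
  })
})

test_that("env tables round-trip with explicit NA handling", {
  env <- env_table(timepoint = c(70L, 72L, 75L),
                   chl_a = c(1.2, NA, 8.4),
                   secchi_depth = c(5.1, 4.2, NA),
                   wind_speed_max = c(31, 80.5, 22),
                   water_level = c(-0.2, 0.4, 0.1),
                   detritus_score = c(0L, 3L, NA),
                   tide_direction = c("rising", "falling", "unknown"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_env_table(env, path)
  got <- read_env_table(path)
  expect_equal(as.data.frame(got), as.data.frame(env))
  expect_error(env_table(70L, detritus_score = 7L), "detritus")
  expect_error(env_table(70L, secchi_depth = 0), "secchi")
})

test_that("protein group tables validate and round-trip", {
  cfg <- sim_config(seed = 3)
  pg <- simulate_metaproteome(cfg, n_groups = 19L)
  expect_identical(nrow(pg$counts), 19L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(pg, path)
  got <- read_protein_groups(path)
  expect_equal(got$counts, pg$counts)
  expect_equal(got$longest_length, pg$longest_length)
  expect_identical(got$taxonomy, pg$taxonomy)
  expect_identical(got$function_category, pg$function_category)
  expect_identical(got$n_peptides, pg$n_peptides)

  expect_error(
    protein_group_table(matrix(1, 1, 1, dimnames = list("g1", "s1")),
                        longest_length = 0, n_peptides = 2L,
                        taxonomy = data.frame(domain = "B", phylum = "P"),
                        function_category = "x"),
    "longest_length")
  expect_error(
    protein_group_table(matrix(1, 1, 1, dimnames = list("g1", "s1")),
                        longest_length = 100, n_peptides = -1L,
                        taxonomy = data.frame(domain = "B", phylum = "P"),
                        function_category = "x"),
    "n_peptides")
})

test_that("networks round-trip via edge TSV and GraphML", {
  cfg <- sim_config(seed = 5, n_background_16s = 10L, n_background_18s = 8L)
  sim <- simulate_bloom(cfg)
  net <- build_network(filter_rare(remove_excluded_taxa(sim$asv_18s), 500),
                       filter_rare(remove_excluded_taxa(sim$asv_16s), 100))
  net <- extract_modules(net)
  expect_gt(nrow(net$edges), 0L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "edge_tsv")
  expect_identical(length(readLines(tsv)) - 1L, nrow(net$edges))
  back <- read_network(tsv, "edge_tsv")
  expect_equal(back$edges[order(back$edges$node_a, back$edges$node_b), ],
               net$edges, tolerance = 1e-12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  got <- read_network(gml, "graphml")
  ord <- function(df) df[order(df$id), c("id", "domain", "taxonomy",
                                         "degree", "module_id")]
  expect_equal(ord(got$nodes), ord(net$nodes), ignore_attr = TRUE)
  eord <- function(df) {
    df <- df[order(df$node_a, df$node_b), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(eord(got$edges), eord(net$edges), tolerance = 1e-9)
})

test_that("a two-node network writes one edge line and an empty one is valid GraphML", {
  nodes <- data.frame(id = c("e1", "b1"), domain = c("18S", "16S"),
                      taxonomy = ";;;;;", degree = 1L, module_id = 1L,
                      stringsAsFactors = FALSE)
  edges <- data.frame(node_a = "e1", node_b = "b1", rho = 0.9,
                      p_raw = 1e-6, p_adj = 1e-5, stringsAsFactors = FALSE)
  net <- bloomnet:::new_co_network(nodes, edges,
                                   list(rho_min = 0.7, alpha = 0.01))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "edge_tsv")
  expect_identical(length(readLines(tsv)), 2L)

  empty <- bloomnet:::new_co_network(nodes[0L, ], edges[0L, ], list())
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(empty, gml, "graphml")
  got <- read_network(gml, "graphml")
  expect_identical(nrow(got$nodes), 0L)
  expect_identical(nrow(got$edges), 0L)
})
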