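#' Default end-to-end run configuration
#'
#' Every stage parameter with its standard value: rare-ASV thresholds of 100
#' (16S) and 500 (18S) reads, edge thresholds rho > 0.7 and BH-adjusted
#' p < 0.01 with the all-pairs adjustment pool, component-based modules, and
#' the default lineage/covariate screen. Amend fields as needed and pass to
#' [run_pipeline()].
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed RNG seed used by simulation stages.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(outdir = "bloomnet_run", seed = 1L) {
  structure(list(
    outdir = outdir,
    simulate = TRUE,
    asv_16s = NULL, asv_18s = NULL, env = NULL, proteome = NULL,
    min_total_16s = 100L,
    min_total_18s = 500L,
    rho_min = 0.7,
    alpha = 0.01,
    adjust_pool = "all_pairs",
    module_method = "components",
    composition_rank = "phylum",
    lineages = c(phylum = "Desulfobacterota", genus = "Nitzschia",
                 genus = "Navicula", genus = "Cocconeis"),
    covariates = c("secchi_depth", "wind_speed_max", "water_level"),
    proteome_lineage = "Desulfobacterota",
    proteome_category = "dissimilatory sulfate reduction",
    sim = list(),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()]. The `lineages`
#' field may be a YAML mapping of rank to name lists, e.g.
#' `lineages: {phylum: [Desulfobacterota], genus: [Nitzschia, Cocconeis]}`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(user$lineages) && is.list(user$lineages)) {
    ranks <- rep(names(user$lineages), lengths(user$lineages))
    user$lineages <- setNames(unlist(user$lineages, use.names = FALSE), ranks)
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full bloom-network pipeline
#'
#' Executes, in order: simulation (or reading of the input tables), taxon
#' exclusion, rare-ASV filtering, cross-kingdom network construction, module
#' extraction and composition, NSAF quantification of the metaproteome, and
#' the environmental association screen. All stage outputs are written to
#' `config$outdir` along with `manifest.json` recording the package version,
#' seed, every parameter and per-stage row/edge counts; given a fixed seed
#' the run is fully deterministic, so the manifest suffices to re-run
#' identically (no timestamps are recorded, keeping reruns byte-identical).
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param quiet Suppress per-stage progress messages on stderr.
#' @return Invisibly, a list with every in-memory stage result (`tables`,
#'   `filtered`, `network`, `composition`, `nsaf`, `assoc`, `manifest`).
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[bloomnet] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "bloomnet",
    version = as.character(utils::packageVersion("bloomnet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("outdir", "sim"))],
    stages = list()
  )

  # --- inputs ---
  truth <- NULL
  if (isTRUE(config$simulate)) {
    say("simulating bloom (seed %d)", config$seed)
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cfg <- stage("simulate", do.call(sim_config, sim_args))
    sim <- stage("simulate", simulate_bloom(cfg))
    a16 <- sim$asv_16s; a18 <- sim$asv_18s; env <- sim$env; truth <- sim$truth
    prot <- stage("simulate", simulate_metaproteome(cfg))
    write_asv_table(a16, file.path(outdir, "asv_16s.tsv"))
    write_asv_table(a18, file.path(outdir, "asv_18s.tsv"))
    write_env_table(env, file.path(outdir, "env.tsv"))
    write_protein_groups(prot, file.path(outdir, "proteome.tsv"))
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    for (f in c("asv_16s", "asv_18s", "env")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("input file for '", f, "' missing: ",
             if (is.null(config[[f]])) "(not set)" else config[[f]],
             call. = FALSE)
      }
    }
    say("reading input tables")
    a16 <- stage("read", read_asv_table(config$asv_16s, "16S"))
    a18 <- stage("read", read_asv_table(config$asv_18s, "18S"))
    env <- stage("read", read_env_table(config$env))
    prot <- if (!is.null(config$proteome)) {
      if (!file.exists(config$proteome)) {
        stop("input file for 'proteome' missing: ", config$proteome,
             call. = FALSE)
      }
      stage("read", read_protein_groups(config$proteome))
    }
  }
  manifest$stages$input <- list(n_asv_16s = nrow(a16$counts),
                                n_asv_18s = nrow(a18$counts),
                                n_timepoints = ncol(a16$counts))

  # --- preprocessing: taxon exclusion first, then rare-ASV filter ---
  say("filtering (exclusion + rare-ASV thresholds %d/%d)",
      config$min_total_16s, config$min_total_18s)
  f16 <- stage("filter", filter_rare(remove_excluded_taxa(a16),
                                     config$min_total_16s))
  f18 <- stage("filter", filter_rare(remove_excluded_taxa(a18),
                                     config$min_total_18s))
  write_asv_table(f16, file.path(outdir, "asv_16s_filtered.tsv"))
  write_asv_table(f18, file.path(outdir, "asv_18s_filtered.tsv"))
  manifest$stages$filter <- list(n_asv_16s = nrow(f16$counts),
                                 n_asv_18s = nrow(f18$counts))

  # --- network ---
  say("building network (rho > %g, adjusted p < %g, pool %s)",
      config$rho_min, config$alpha, config$adjust_pool)
  net <- stage("network", build_network(f18, f16, rho_min = config$rho_min,
                                        alpha = config$alpha,
                                        adjust_pool = config$adjust_pool))
  net <- stage("modules", extract_modules(net, config$module_method))
  comp <- stage("modules", module_composition(net, config$composition_rank))
  write_network(net, file.path(outdir, "network.graphml"), "graphml")
  write_network(net, file.path(outdir, "edges.tsv"), "edge_tsv")
  utils::write.table(comp$composition, file.path(outdir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$network <- list(
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    n_modules = if (nrow(net$nodes) > 0L) max(net$nodes$module_id) else 0L,
    n_constant_dropped = net$params$n_constant_dropped
  )

  # --- metaproteome NSAF ---
  nsaf_tab <- NULL
  if (!is.null(prot)) {
    say("quantifying metaproteome (NSAF)")
    prot_ok <- stage("nsaf", valid_detection_filter(prot))
    m <- stage("nsaf", nsaf(prot_ok))
    share <- taxon_share(m, prot_ok, config$proteome_lineage,
                         average = "over_all_samples")
    frac <- within_taxon_function_fraction(m, prot_ok,
                                           config$proteome_lineage,
                                           config$proteome_category)
    nsaf_tab <- data.frame(group_id = rownames(m), m, check.names = FALSE,
                           stringsAsFactors = FALSE)
    utils::write.table(nsaf_tab, file.path(outdir, "nsaf.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$nsaf <- list(
      n_groups = nrow(m), n_samples = ncol(m),
      lineage = config$proteome_lineage, lineage_mean_share = share,
      within_lineage_category_fraction = frac
    )
  }

  # --- environmental associations ---
  say("environmental association screen")
  assoc16 <- stage("envassoc", assoc_screen(f16, env, config$lineages,
                                            config$covariates))
  assoc18 <- stage("envassoc", assoc_screen(f18, env, config$lineages,
                                            config$covariates))
  assoc16$marker <- "16S"; assoc18$marker <- "18S"
  assoc <- rbind(assoc16, assoc18)
  utils::write.table(assoc, file.path(outdir, "assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  manifest$stages$envassoc <- list(
    n_fits = nrow(assoc), n_significant = sum(assoc$significant, na.rm = TRUE)
  )

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done: %s", outdir)
  invisible(list(tables = list(asv_16s = a16, asv_18s = a18, env = env,
                               proteome = prot, truth = truth),
                 filtered = list(asv_16s = f16, asv_18s = f18),
                 network = net, composition = comp, nsaf = nsaf_tab,
                 assoc = assoc, manifest = manifest))
}
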