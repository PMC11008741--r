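#' Specify one planted co-occurrence module
#'
#' A module is a set of eukaryote (18S) and bacterial (16S) taxa that share a
#' Gaussian bloom pulse in time; sharing the temporal profile is exactly what
#' makes them a recoverable co-occurrence module downstream. A module may
#' carry a rare guild: a low-abundance bacterial lineage (e.g. a
#' sulfate-reducer-like guild) that tracks the module's pulse.
#'
#' @param name Module label, recorded in the truth map.
#' @param n_euk,n_bac Number of 18S / 16S member ASVs (each >= 1).
#' @param peak_day Julian day of the pulse maximum.
#' @param width_days Gaussian standard deviation of the pulse, days.
#' @param mean_relabund Target mean relative abundance of the module within
#'   its marker table, in (0, 1).
#' @param rare_guild Optional list with `n_taxa`, `mean_relabund` and
#'   `lineage_label` describing a planted low-abundance 16S guild sharing the
#'   module's pulse.
#' @return An object of class `module_spec`.
#' @export
module_spec <- function(name, n_euk, n_bac, peak_day, width_days,
                        mean_relabund, rare_guild = NULL) {
  if (n_euk < 1L || n_bac < 1L) stop("modules need n_euk >= 1 and n_bac >= 1")
  if (mean_relabund <= 0 || mean_relabund >= 1) {
    stop("mean_relabund must lie in (0, 1)")
  }
  if (width_days <= 0) stop("width_days must be positive")
  if (!is.null(rare_guild)) {
    stopifnot(all(c("n_taxa", "mean_relabund", "lineage_label") %in% names(rare_guild)),
              rare_guild$n_taxa >= 1L, rare_guild$mean_relabund > 0,
              rare_guild$mean_relabund < 1)
  }
  structure(list(name = name, n_euk = as.integer(n_euk),
                 n_bac = as.integer(n_bac), peak_day = peak_day,
                 width_days = width_days, mean_relabund = mean_relabund,
                 rare_guild = rare_guild),
            class = "module_spec")
}

#' Default planted modules for a spring bloom
#'
#' Two successional pulses around the chlorophyll peak: an early
#' diatom-dominated module and a late dinoflagellate-dominated module,
#' peaking roughly 30 days apart, plus a rare (0.38% mean) sulfate-reducer
#' guild riding the diatom pulse.
#'
#' @param bloom_peak_day Julian day of the chlorophyll a maximum.
#' @return List of two [module_spec()] objects.
#' @export
default_modules <- function(bloom_peak_day = 116) {
  list(
    module_spec("diatom_bloom", n_euk = 8L, n_bac = 25L,
                peak_day = bloom_peak_day - 16, width_days = 9,
                mean_relabund = 0.35,
                rare_guild = list(n_taxa = 11L, mean_relabund = 0.0038,
                                  lineage_label = "Desulfobacterota")),
    module_spec("dinoflagellate_bloom", n_euk = 6L, n_bac = 20L,
                peak_day = bloom_peak_day + 14, width_days = 9,
                mean_relabund = 0.25)
  )
}

#' Configuration of the synthetic spring bloom
#'
#' Full parameterisation of the generator. Defaults mirror the study design
#' they emulate: 51 near-daily timepoints across Julian days 63-149, a
#' chlorophyll peak at day 116, sequencing depths of 50 000 (16S) and
#' 30 000 (18S) reads per timepoint, and the two-module succession of
#' [default_modules()]. All of these are configuration, not constants.
#'
#' @param n_timepoints Number of sampling days (>= 10), default 51.
#' @param day_start,day_end First/last Julian day, defaults 63 and 149.
#' @param bloom_peak_day Julian day of peak chlorophyll, default 116.
#' @param modules List of [module_spec()]s; module mean relative abundances
#'   (plus guilds, per marker) must sum to < 1, the remainder going to
#'   unstructured background taxa.
#' @param depth_16s,depth_18s Reads per timepoint (>= 1000).
#' @param overdispersion Dirichlet concentration scalar; `Inf` (default)
#'   gives plain multinomial sampling, finite values add compositional
#'   overdispersion.
#' @param noise_sd Standard deviation of the lognormal day-to-day noise on
#'   latent abundances (natural-log scale), default 0.2.
#' @param benthic_fraction Fraction of background taxa flagged benthic per
#'   marker, default 0.1.
#' @param wind_coupling Coefficient linking standardised wind speed to
#'   benthic latent abundance (`exp(wind_coupling * z_wind)`), default 1.
#'   The resuspension model is phenomenological; no quantitative coupling is
#'   available to calibrate against.
#' @param n_background_16s,n_background_18s Unstructured background taxa per
#'   marker, defaults 30 and 15.
#' @param n_organelle_16s Planted chloroplast/mitochondrial 16S ASVs
#'   (removed by preprocessing), default 3.
#' @param n_metazoan_18s Planted metazoan 18S ASVs, default 2.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 51L, day_start = 63L, day_end = 149L,
                       bloom_peak_day = 116L,
                       modules = default_modules(bloom_peak_day),
                       depth_16s = 50000L, depth_18s = 30000L,
                       overdispersion = Inf, noise_sd = 0.2,
                       benthic_fraction = 0.1, wind_coupling = 1.0,
                       n_background_16s = 30L, n_background_18s = 15L,
                       n_organelle_16s = 3L, n_metazoan_18s = 2L,
                       seed = 1L) {
  cfg <- structure(list(
    n_timepoints = as.integer(n_timepoints), day_start = as.integer(day_start),
    day_end = as.integer(day_end), bloom_peak_day = as.integer(bloom_peak_day),
    modules = modules, depth_16s = as.integer(depth_16s),
    depth_18s = as.integer(depth_18s), overdispersion = overdispersion,
    noise_sd = noise_sd, benthic_fraction = benthic_fraction,
    wind_coupling = wind_coupling,
    n_background_16s = as.integer(n_background_16s),
    n_background_18s = as.integer(n_background_18s),
    n_organelle_16s = as.integer(n_organelle_16s),
    n_metazoan_18s = as.integer(n_metazoan_18s),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config`.
#' @return `cfg` if valid, else an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (cfg$depth_16s < 1000L || cfg$depth_18s < 1000L) {
    stop("sequencing depths must be >= 1000")
  }
  if (cfg$noise_sd < 0 || cfg$benthic_fraction < 0 || cfg$benthic_fraction > 1) {
    stop("noise_sd must be >= 0 and benthic_fraction in [0, 1]")
  }
  if (cfg$overdispersion <= 0) stop("overdispersion must be positive (Inf = multinomial)")
  if (cfg$day_end <= cfg$day_start) stop("day_end must exceed day_start")
  if (length(cfg$modules) < 1L ||
      !all(vapply(cfg$modules, inherits, logical(1L), "module_spec"))) {
    stop("modules must be a non-empty list of module_spec objects")
  }
  share_16s <- sum(vapply(cfg$modules, function(m) {
    m$mean_relabund + if (is.null(m$rare_guild)) 0 else m$rare_guild$mean_relabund
  }, numeric(1L)))
  share_18s <- sum(vapply(cfg$modules, `[[`, numeric(1L), "mean_relabund"))
  if (share_16s >= 1 || share_18s >= 1) {
    stop("module mean relative abundances must sum to < 1 per marker")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d timepoints (days %d-%d), %d modules, seed %d\n",
              x$n_timepoints, x$day_start, x$day_end, length(x$modules),
              x$seed))
  invisible(x)
}

.diatom_genera <- c("Thalassiosira", "Thalassionema", "Chaetoceros",
                    "Skeletonema", "Brockmanniella", "Rhizosolenia",
                    "Ditylum", "Coscinodiscus")
.dino_genera <- c("Gymnodinium", "Heterocapsa", "Prorocentrum", "Tripos",
                  "Alexandrium", "Scrippsiella")
.bact_lineages <- data.frame(
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Bacteroidota", "Verrucomicrobiota", "Planctomycetota",
             "Actinobacteriota"),
  family = c("Rhodobacteraceae", "Spongiibacteraceae", "Methylophagaceae",
             "Flavobacteriaceae", "Rubritaleaceae", "Phycisphaeraceae",
             "Ilumatobacteraceae"),
  genus = c("Sulfitobacter", "Spongiibacter", "Methylophaga", "Polaribacter",
            "Persicirhabdus", "Phycisphaera", "Ilumatobacter"),
  stringsAsFactors = FALSE
)
.desulfo_families <- c("Desulfosarcinaceae", "Desulfocapsaceae",
                       "Desulfobulbaceae", "Sva1033")
.benthic_genera <- c("Nitzschia", "Navicula", "Cocconeis")

.gaussian_pulse <- function(days, peak, width) {
  exp(-((days - peak)^2) / (2 * width^2))
}

# per-timepoint counts at fixed depth: multinomial, or Dirichlet-multinomial
# when the concentration is finite
.draw_counts <- function(latent, depth, overdispersion) {
  k <- nrow(latent)
  counts <- matrix(0, k, ncol(latent), dimnames = dimnames(latent))
  for (j in seq_len(ncol(latent))) {
    p <- latent[, j] / sum(latent[, j])
    if (is.finite(overdispersion)) {
      g <- stats::rgamma(k, shape = overdispersion * p, rate = 1)
      if (sum(g) == 0) g <- p   # degenerate draw; fall back to the mean
      p <- g / sum(g)
    }
    counts[, j] <- stats::rmultinom(1L, size = depth, prob = p)
  }
  counts
}

#' Simulate a spring-bloom amplicon time series with planted structure
#'
#' Generates paired 16S and 18S ASV count tables, an environmental covariate
#' table and a truth map. Latent abundance of each module member is a
#' Gaussian pulse centred at the module's peak day, times a taxon-specific
#' lognormal multiplier, times lognormal day-to-day noise; background taxa
#' follow stationary lognormal series; benthic-flagged taxa are additionally
#' multiplied by `exp(wind_coupling * z_wind)` where `z_wind` is the
#' standardised simulated wind series (wind-driven resuspension). Counts are
#' drawn multinomially (Dirichlet-multinomially for finite overdispersion) at
#' the configured depth per timepoint, so the data are deliberately
#' compositional — the same pitfall the real correlations face. Chlorophyll a
#' is proportional to the summed module pulses plus noise; wind follows an
#' AR(1) process with three storm spikes (> 75 km/h) in the first half of the
#' series. Everything is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `asv_16s`, `asv_18s` ([asv_table()]s), `env`
#'   ([env_table()]), and `truth` (data frame: `asv_id`, `marker`, `module`
#'   — a planted module name or `"background"` — and `role` in
#'   core/guild/background/organelle/metazoan; benthic background taxa keep
#'   role `background` but are flagged in the tables).
#' @export
simulate_bloom <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  days <- round(seq(config$day_start, config$day_end,
                    length.out = config$n_timepoints))
  if (anyDuplicated(days)) stop("timepoint spacing too fine for integer days")
  nd <- length(days)
  day_lab <- as.character(days)

  # --- environment: wind first (it feeds back into benthic latents) ---
  wind <- numeric(nd)
  wind[1L] <- 30
  for (t in 2L:nd) wind[t] <- 30 + 0.6 * (wind[t - 1L] - 30) + stats::rnorm(1L, 0, 10)
  storm_at <- sample(seq_len(floor(nd / 2)), 3L)
  wind[storm_at] <- wind[storm_at] + stats::runif(3L, 50, 65)
  wind <- pmax(2, wind)
  z_wind <- as.numeric(scale(wind))

  pulses <- lapply(config$modules, function(m) {
    p <- .gaussian_pulse(days, m$peak_day, m$width_days)
    p / mean(p)   # unit time-average, so amplitude = mean_relabund
  })
  combined <- Reduce(`+`, Map(function(m, p) m$mean_relabund * p,
                              config$modules, pulses))

  day_noise <- function() exp(stats::rnorm(nd, 0, config$noise_sd))
  member_weights <- function(k) {
    w <- stats::rlnorm(k, 0, 0.5)
    w / sum(w)
  }

  # --- assemble per-marker latent matrices ---
  build_marker <- function(marker) {
    is16 <- marker == "16S"
    rows <- list(); tax <- list(); flag <- list(); truth <- list()
    add <- function(id, latent, taxonomy, flags, module, role) {
      rows[[id]] <<- latent
      tax[[id]] <<- taxonomy
      flag[[id]] <<- flags
      truth[[id]] <<- data.frame(asv_id = id, marker = marker,
                                 module = module, role = role,
                                 stringsAsFactors = FALSE)
    }
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("a%s_%04d", if (is16) "16" else "18", counter)
    }
    no_flags <- c(is_organelle = FALSE, is_metazoan = FALSE, is_benthic = FALSE)

    for (mi in seq_along(config$modules)) {
      m <- config$modules[[mi]]
      pulse <- pulses[[mi]]
      n_mem <- if (is16) m$n_bac else m$n_euk
      w <- member_weights(n_mem)
      for (i in seq_len(n_mem)) {
        latent <- m$mean_relabund * pulse * w[i] * day_noise()
        taxonomy <- if (is16) {
          lin <- .bact_lineages[(i - 1L) %% nrow(.bact_lineages) + 1L, ]
          c(domain = "Bacteria", phylum = lin$phylum, class = "",
            order = "", family = lin$family, genus = lin$genus)
        } else if (mi == 1L) {
          c(domain = "Eukaryota", phylum = "Bacillariophyta",
            class = "Bacillariophyceae", order = "", family = "",
            genus = .diatom_genera[(i - 1L) %% length(.diatom_genera) + 1L])
        } else {
          c(domain = "Eukaryota", phylum = "Dinoflagellata",
            class = "Dinophyceae", order = "", family = "",
            genus = .dino_genera[(i - 1L) %% length(.dino_genera) + 1L])
        }
        add(next_id(), latent, taxonomy, no_flags, m$name, "core")
      }
      if (is16 && !is.null(m$rare_guild)) {
        g <- m$rare_guild
        wg <- member_weights(g$n_taxa)
        for (i in seq_len(g$n_taxa)) {
          latent <- g$mean_relabund * pulse * wg[i] * day_noise()
          fam <- .desulfo_families[(i - 1L) %% length(.desulfo_families) + 1L]
          taxonomy <- c(domain = "Bacteria", phylum = g$lineage_label,
                        class = "", order = "", family = fam,
                        genus = if (fam == "Desulfosarcinaceae") "Desulfosarcina" else "")
          add(next_id(), latent, taxonomy, no_flags, m$name, "guild")
        }
      }
    }

    guild_share <- if (is16) {
      sum(vapply(config$modules, function(m) {
        if (is.null(m$rare_guild)) 0 else m$rare_guild$mean_relabund
      }, numeric(1L)))
    } else 0
    module_share <- sum(vapply(config$modules, `[[`, numeric(1L),
                               "mean_relabund"))
    bg_share <- 1 - module_share - guild_share

    n_bg <- if (is16) config$n_background_16s else config$n_background_18s
    n_extra <- if (is16) config$n_organelle_16s else config$n_metazoan_18s
    n_benthic <- max(1L, round(config$benthic_fraction * n_bg))
    wb <- member_weights(n_bg + n_extra)
    for (i in seq_len(n_bg)) {
      benthic <- i <= n_benthic
      latent <- bg_share * wb[i] * day_noise()
      if (benthic) latent <- latent * exp(config$wind_coupling * z_wind)
      taxonomy <- if (is16) {
        lin <- .bact_lineages[(i - 1L) %% nrow(.bact_lineages) + 1L, ]
        c(domain = "Bacteria", phylum = lin$phylum, class = "", order = "",
          family = lin$family, genus = lin$genus)
      } else if (benthic) {
        c(domain = "Eukaryota", phylum = "Bacillariophyta",
          class = "Bacillariophyceae", order = "", family = "",
          genus = .benthic_genera[(i - 1L) %% length(.benthic_genera) + 1L])
      } else {
        c(domain = "Eukaryota", phylum = "Haptophyta", class = "", order = "",
          family = "", genus = "")
      }
      flags <- no_flags
      flags["is_benthic"] <- benthic
      add(next_id(), latent, taxonomy, flags, "background", "background")
    }
    for (i in seq_len(n_extra)) {
      latent <- bg_share * wb[n_bg + i] * day_noise()
      if (is16) {
        taxonomy <- c(domain = "Bacteria", phylum = "Cyanobacteria",
                      class = "Cyanobacteriia", order = "Chloroplast",
                      family = "", genus = "")
        flags <- no_flags; flags["is_organelle"] <- TRUE
        role <- "organelle"
      } else {
        taxonomy <- c(domain = "Eukaryota", phylum = "Metazoa",
                      class = "Copepoda", order = "", family = "", genus = "")
        flags <- no_flags; flags["is_metazoan"] <- TRUE
        role <- "metazoan"
      }
      add(next_id(), latent, taxonomy, flags, "background", role)
    }

    latent <- do.call(rbind, rows)
    colnames(latent) <- day_lab
    counts <- .draw_counts(latent, if (is16) config$depth_16s else config$depth_18s,
                           config$overdispersion)
    taxonomy <- as.data.frame(do.call(rbind, tax), stringsAsFactors = FALSE)
    rownames(taxonomy) <- NULL
    flags <- as.data.frame(do.call(rbind, flag))
    rownames(flags) <- NULL
    list(table = asv_table(counts, marker = marker, taxonomy = taxonomy,
                           flags = flags),
         truth = do.call(rbind, truth))
  }

  m16 <- build_marker("16S")
  m18 <- build_marker("18S")

  chl <- 1 + 14 * (combined / max(combined)) * exp(stats::rnorm(nd, 0, 0.1))
  secchi <- pmax(0.5, 7 - 4 * combined / max(combined) + stats::rnorm(nd, 0, 0.4))
  water_level <- round(stats::rnorm(nd, 0, 0.8), 2)
  detritus <- pmin(6L, pmax(0L, as.integer(round(1.5 + 1.2 * z_wind +
                                                   stats::rnorm(nd, 0, 0.8)))))
  tide <- sample(c("rising", "falling"), nd, replace = TRUE)
  env <- env_table(timepoint = days, chl_a = round(chl, 3),
                   secchi_depth = round(secchi, 2),
                   wind_speed_max = round(wind, 1),
                   water_level = water_level, detritus_score = detritus,
                   tide_direction = tide)

  truth <- rbind(m16$truth, m18$truth)
  rownames(truth) <- NULL
  list(asv_16s = m16$table, asv_18s = m18$table, env = env, truth = truth,
       config = config)
}

.function_categories <- c("energy production and conversion",
                          "carbohydrate transport and metabolism",
                          "translation and ribosome biogenesis",
                          "amino acid transport and metabolism",
                          "cellular processes and signaling",
                          "posttranslational modification and chaperones")

#' Simulate a three-timepoint particle metaproteome
#'
#' Draws exclusive unique spectrum counts multinomially over protein groups,
#' with the eukaryote share of spectra interpolating linearly between
#' `euk_fraction_start` and `euk_fraction_end` across the requested
#' timepoints (the bloom-decline signature: eukaryote proteins dominate early
#' and bacteria catch up late). A configurable subset of bacterial groups
#' carries the lineage `Desulfobacterota`, a fixed small share of total
#' spectra, and of these a subset is tagged with the function category
#' `"dissimilatory sulfate reduction"`. Group lengths are uniform on
#' 100-1500 aa and every emitted group has at least two matched peptides.
#'
#' @param config A [sim_config()] (supplies the default seed).
#' @param timepoints Julian days of the sampled proteomes, default
#'   `c(107, 128, 144)`.
#' @param euk_fraction_start,euk_fraction_end Eukaryote spectrum share at the
#'   first/last timepoint, strictly inside (0, 1); defaults 0.9 and 0.7.
#' @param n_groups Total number of protein groups (>= 4), default 150.
#' @param n_replicates Technical replicates per timepoint, default 3.
#' @param total_spectra Spectra per sample, default 20000.
#' @param desulfo_share Share of total spectra carried by the
#'   `Desulfobacterota` groups, default 0.0014.
#' @param n_desulfo Number of `Desulfobacterota` groups, default 19.
#' @param n_desulfo_sulfate How many of those are dissimilatory sulfate
#'   reduction enzymes, default 7; they carry `sulfate_fraction` of the
#'   guild's spectra.
#' @param sulfate_fraction Share of the guild's spectra in the sulfate
#'   reduction category, default 0.32.
#' @param seed RNG seed, default `config$seed`.
#' @return A [protein_group_table()] with samples labelled `d<day>_r<rep>`.
#' @export
simulate_metaproteome <- function(config, timepoints = c(107L, 128L, 144L),
                                  euk_fraction_start = 0.9,
                                  euk_fraction_end = 0.7,
                                  n_groups = 150L, n_replicates = 3L,
                                  total_spectra = 20000L,
                                  desulfo_share = 0.0014, n_desulfo = 19L,
                                  n_desulfo_sulfate = 7L,
                                  sulfate_fraction = 0.32,
                                  seed = config$seed) {
  if (n_groups < 4L) stop("n_groups must be >= 4")
  for (f in c(euk_fraction_start, euk_fraction_end)) {
    if (f <= 0 || f >= 1) {
      stop("eukaryote fractions must lie strictly inside (0, 1)")
    }
  }
  bac_share_min <- 1 - max(euk_fraction_start, euk_fraction_end)
  if (desulfo_share >= bac_share_min) {
    stop("desulfo_share must be smaller than the bacterial spectrum share")
  }
  set.seed(seed)

  n_euk <- max(1L, round(0.6 * n_groups))
  n_desulfo <- min(n_desulfo, n_groups - n_euk - 1L)
  if (n_desulfo < 1L) n_desulfo <- 1L
  n_desulfo_sulfate <- min(n_desulfo_sulfate, n_desulfo)
  n_bac_other <- n_groups - n_euk - n_desulfo
  if (n_bac_other < 1L) stop("n_groups too small for the requested group split")

  class_of <- c(rep("euk", n_euk), rep("bac", n_bac_other),
                rep("desulfo_sulfate", n_desulfo_sulfate),
                rep("desulfo_other", n_desulfo - n_desulfo_sulfate))
  ids <- sprintf("pg_%04d", seq_len(n_groups))
  w <- stats::rlnorm(n_groups, 0, 0.8)
  # normalise weights within each group class, keeping the group order
  w_norm <- stats::ave(w, class_of, FUN = function(v) v / sum(v))

  lengths_aa <- as.integer(round(stats::runif(n_groups, 100, 1500)))
  n_pep <- 2L + stats::rpois(n_groups, 3)
  fun <- sample(.function_categories, n_groups, replace = TRUE)
  fun[class_of == "desulfo_sulfate"] <- "dissimilatory sulfate reduction"
  domain <- ifelse(class_of == "euk", "Eukaryota", "Bacteria")
  phylum <- character(n_groups)
  phylum[class_of == "euk"] <- rep_len(c("Bacillariophyta", "Bacillariophyta",
                                         "Bacillariophyta", "Dinoflagellata"),
                                       n_euk)
  phylum[class_of == "bac"] <- rep_len(c("Proteobacteria", "Bacteroidota",
                                         "Planctomycetota"), n_bac_other)
  phylum[startsWith(class_of, "desulfo")] <- "Desulfobacterota"

  euk_frac <- seq(euk_fraction_start, euk_fraction_end,
                  length.out = length(timepoints))
  samples <- as.vector(t(outer(timepoints, seq_len(n_replicates),
                               function(d, r) sprintf("d%d_r%d", d, r))))
  counts <- matrix(0, n_groups, length(samples),
                   dimnames = list(ids, samples))
  col <- 0L
  for (ti in seq_along(timepoints)) {
    f <- euk_frac[ti]
    class_mass <- c(
      euk = f,
      bac = 1 - f - desulfo_share,
      desulfo_sulfate = desulfo_share * sulfate_fraction,
      desulfo_other = desulfo_share * (1 - sulfate_fraction)
    )
    if (n_desulfo == n_desulfo_sulfate) {
      class_mass["desulfo_sulfate"] <- desulfo_share
    }
    prob <- w_norm * class_mass[class_of]
    prob <- prob / sum(prob)
    for (r in seq_len(n_replicates)) {
      col <- col + 1L
      counts[, col] <- stats::rmultinom(1L, total_spectra, prob)
    }
  }

  protein_group_table(
    counts = counts,
    longest_length = lengths_aa,
    taxonomy = data.frame(domain = domain, phylum = phylum,
                          stringsAsFactors = FALSE),
    function_category = fun,
    n_peptides = n_pep
  )
}
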