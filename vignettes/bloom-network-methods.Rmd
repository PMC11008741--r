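---
title: "Cross-kingdom co-occurrence networks for bloom particle microbiomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom co-occurrence networks for bloom particle microbiomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomnet)
```

## The analysis problem

During a spring phytoplankton bloom, the particle fraction (> 10 µm) of the
water column carries a mixed community: living and senescent phytoplankton,
their attached bacteria, and material resuspended from the sediment. A
near-daily amplicon time series — 16S rRNA gene ASVs for bacteria, 18S for
eukaryotes — lets us ask which bacteria rise and fall *together with* which
eukaryotes, without claiming physical attachment: temporal co-occurrence is
an association screen, not an interaction assay.

bloomnet implements that screen end to end:

1. **Preprocessing** — remove reads that are not community members
   (chloroplast/mitochondrial 16S, metazoan 18S), then drop rare ASVs whose
   total read count across the series falls below a floor (100 reads for
   16S, 500 for 18S by default; the boundary value itself survives, since
   removal is by strict `<`).
2. **Network construction** — Spearman rank correlation between every ASV
   pair, Benjamini–Hochberg (BH) adjustment over the pool of all pairs,
   then an edge for each 18S–16S pair with `rho > 0.7` and adjusted
   `p < 0.01` (both strict, positive correlations only). The resulting graph
   is bipartite by construction.
3. **Modules** — connected components of the thresholded graph, labelled in
   decreasing size order.
4. **Metaproteome quantification** — normalized spectral abundance factors
   (NSAF) for protein groups, plus taxon shares and the
   "fraction of a taxon's proteome in a function category" statistic.
5. **Environmental regressions** — simple least-squares fits of lineage
   relative abundance against covariates such as wind speed, Secchi depth
   and water level, the standard screen for benthic–pelagic coupling
   (wind-driven resuspension).

## The statistical model

**Spearman rho** is computed as the Pearson correlation of average ranks
(ties receive the mean of the ranks they span). The two-sided p-value uses
the t approximation

$$t = \rho\sqrt{\frac{n-2}{1-\rho^2}} \sim t_{n-2},$$

which is the approximation common rank-correlation implementations use and
is accurate at the series lengths involved here (n ≈ 51). Exactly monotone
pairs give p = 0 by convention. A constant series has no rank variation, so
such pairs are dropped from the analysis (counted, never propagated as NaN).

**BH adjustment** is the literal step-up procedure: sort the m p-values
ascending, form `q_(i) = p_(i) * m / i`, enforce monotonicity by a
cumulative minimum from the largest index down, cap at 1, and return in the
original order. The default adjustment pool is *all* ASV pairs (within- and
cross-domain), mirroring the procedure of correlating all remaining ASVs
first and restricting to cross-kingdom pairs only at the edge-selection
step; `adjust_pool = "cross_domain_only"` gives the statistically tighter
alternative where only pairs that can become edges enter the pool. Both are
exposed because the two readings produce different adjusted p-values; the
run's active rule is recorded in the network object and the manifest.

**Edge thresholds** are strict on both sides (`rho > 0.7`, adjusted
`p < 0.01`), and `rho_min > 0` is enforced: the network is built from
significant *positive* co-occurrences only. Negative and non-significant
correlations are retained in the `records` table of the result for
inspection but never become edges.

**Modules** default to connected components because they are deterministic
and parameter-free, and because temporally separated bloom pulses produce
exactly the "distinct module" structure components detect. Louvain
modularity optimisation (`method = "louvain"`) is available for dense
networks where components fuse; note it is stochastic in general and
component-based module ids should be preferred for reproducibility.

**NSAF.** For protein group g in sample s with exclusive unique spectrum
count `c[g,s]` and longest-member protein length `L[g]` (amino acids),

$$\mathrm{SAF}[g,s] = c[g,s] / L[g], \qquad
  \mathrm{NSAF}[g,s] = \mathrm{SAF}[g,s] \Big/ \sum_g \mathrm{SAF}[g,s],$$

so each sample's NSAF column sums to 1. Groups are only treated as validly
detected with at least two matched peptides; optional protein/peptide
identification probability columns are filtered at 0.99/0.95 when present
(they are upstream search-engine outputs and often unavailable, hence
optional). "Averaged over all time points" is implemented as the unweighted
mean of per-sample shares with replicates first averaged within their
timepoint; both replicate-handling modes are exposed
(`replicates_first`). The within-taxon function fraction pools NSAF across
all samples before taking the ratio, and is abundance-weighted — it is a
share of protein *abundance*, not a count of protein groups.

**Environmental regressions** use ordinary least squares per (lineage,
covariate) pair with pairwise-complete observations and report slope, R²,
and the F-test p-value; fits are flagged significant at p < 0.01. No
multiple-testing correction is applied by default (the screen mirrors
standard single-covariate reporting); a BH column is available with
`bh = TRUE`. A `lag` argument shifts the covariate series for
lead/lag exploration; the default is same-day (lag 0).

## Counts or proportions?

Spearman correlation is invariant to monotone transforms of each series
separately, but converting counts to per-sample proportions is *not* a
per-series monotone transform when library sizes differ across samples. The
choice therefore matters. The default correlates relative abundances
(`use_relative = TRUE`), recomputed on the filtered table; raw-count mode is
available. Neither choice removes compositional coupling — see the
limitations below.

## The synthetic bloom generator

`simulate_bloom()` produces data with *planted, recoverable structure* so
every downstream stage can be validated without any external dataset:

* **Succession**: two modules by default — an early diatom-dominated pulse
  and a late dinoflagellate-dominated pulse, Gaussian in time, peaking 30
  days apart (Julian days 100 and 130 around a day-116 chlorophyll peak),
  each pulse shared by that module's 18S and 16S members. Gaussian pulses
  with lognormal noise were chosen over autoregressive dynamics because the
  single-peak phenology makes module co-membership equal
  temporal-profile sharing — which is precisely what Spearman co-occurrence
  detects, so planted membership is a meaningful ground truth.
* **Rare guild**: a planted 11-taxon sulfate-reducer-like 16S guild
  (`Desulfobacterota` lineage) rides the diatom pulse at a mean relative
  abundance of 0.38% — rare enough to test that the rare-ASV floor and the
  network still pick it up, and planted exclusively in the diatom module so
  module-exclusivity statements can be verified against truth. Its realised
  mean relative abundance sits somewhat below the nominal target (about
  0.29% at default settings) because the guild peaks exactly when the
  closure denominator is swollen by the bloom modules; the target is a
  latent-scale parameter, not a guaranteed compositional outcome.
* **Compositionality, deliberately**: counts are multinomial at fixed depth
  (50 000 reads for 16S, 30 000 for 18S per timepoint), or
  Dirichlet-multinomial for finite `overdispersion`. Proportions therefore
  share a denominator, exactly the pitfall the real analysis faces. One
  visible consequence: stationary background taxa become mutually
  positively correlated (when the bloom modules swell, everything else
  shrinks together), so the background forms its own network component.
  The recovery score is computed on planted module members only, where
  truth is defined.
* **Benthic coupling**: a configurable fraction of background taxa is
  flagged benthic (18S benthic taxa get the classic benthic diatom genera
  *Nitzschia*, *Navicula*, *Cocconeis*), and their latent abundance is
  multiplied by `exp(wind_coupling * z_wind)` with wind simulated as an
  AR(1) series (mean 30 km/h, three storm spikes above 75 km/h in the first
  half of the series). No quantitative resuspension model exists to
  calibrate against, so `wind_coupling` is a free parameter; the default of
  1.0 makes the planted effect clearly detectable by the regression screen
  (the acceptance script reports the realised R² against wind), stronger
  than the weak-to-moderate couplings typically reported in the field — the
  goal is a recoverable planted effect, not a field-calibrated effect size.
* **Removal fodder**: a few chloroplast-order 16S ASVs and metazoan 18S
  ASVs are planted so the exclusion step has real work to do.

`simulate_metaproteome()` draws spectrum counts multinomially over protein
groups for three timepoints (days 107/128/144, three replicates each, 20 000
spectra per sample by default), with the eukaryote share of spectra
interpolating linearly from 0.9 to 0.7 across the timepoints, a
`Desulfobacterota` guild of 19 groups at 0.14% of spectra, and 7 of those
groups tagged "dissimilatory sulfate reduction" carrying 32% of the guild's
spectra. Lengths are uniform on 100–1500 aa. Because NSAF reweights groups
by inverse length, NSAF-scale readouts of these planted *spectrum-scale*
fractions scatter around the planted values — noticeably so for the
19-group guild, where a handful of short or long proteins can move the
within-guild enzyme share by tens of percentage points at a single seed.
This is a faithful property of length-normalised quantification at small
group counts, not an estimation defect.

What the generator does *not* emulate: sequence-level error, taxonomic
misclassification, autocorrelated residual dynamics, tidal physics, true
within-domain interactions, and any physical algal–bacterial attachment.
Passing the recovery tests therefore shows the pipeline is correct and
sensitive under clean single-pulse phenology; it does not certify
performance on real bloom data with messier dynamics.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_total` (16S / 18S) | 100 / 500 | reads | rare-ASV floor; boundary kept (strict `<` removal) |
| `rho_min` | 0.7 | – | strict positive-correlation edge threshold |
| `alpha` | 0.01 | – | strict threshold on BH-adjusted p |
| `adjust_pool` | `all_pairs` | – | BH pool; `cross_domain_only` is the tighter reading |
| `n_timepoints` | 51 | days | near-daily sampling across the bloom |
| `depth_16s` / `depth_18s` | 50 000 / 30 000 | reads | per-timepoint library size |
| `noise_sd` | 0.2 | ln-scale sd | day-to-day lognormal noise on latents |
| `wind_coupling` | 1.0 | per sd wind | benthic resuspension strength (free parameter) |
| `overdispersion` | `Inf` | – | Dirichlet concentration; `Inf` = multinomial |

## Numerical choices and degenerate inputs

* Correlations are clamped to [-1, 1] before the p-value to absorb
  floating-point overshoot; `rho = ±1` maps to p = 0.
* Constant series (rank-degenerate) are excluded from the BH pool and can
  never form edges; the count of dropped series is recorded in
  `params$n_constant_dropped`.
* Module ids are relabelled 1..k by descending component size with ties
  broken by the lexicographically smallest member id, so labellings are
  stable across runs and row permutations.
* Zero-sum count columns and zero-spectrum samples are errors that name the
  offending timepoint/sample rather than silently producing NaNs.
* Tables are validated on construction *and* on read; files violating an
  invariant are rejected with a located error, never coerced.
* `run_pipeline()` writes no timestamps into its outputs, so a fixed seed
  makes reruns byte-identical; the manifest records the package version,
  seed, all parameters, and per-stage row/edge counts.

## Validation strategy and problem sizes

The test suite validates each primitive against an independently coded
oracle: Spearman against rank-by-sorting plus sufficient-statistics Pearson
(200 random tied pairs at n = 51, 1e-12 on rho), BH against the literal
step-up recursion (1000 random vectors up to m = 500, exact), the full
network against a brute-force enumerate–correlate–adjust–threshold loop
(about 30 × 90 ASVs, both adjustment pools), OLS against the closed form
from Σx, Σy, Σxy, Σx², Σy² (100 random fixtures, 1e-10), and NSAF against
hand arithmetic. Parameter recovery is scored as the median adjusted Rand
index between planted and recovered module membership over 20 simulator
seeds (threshold 0.9), plus the fraction of seeds in which the planted rare
guild sits exclusively in the diatom module (threshold 0.8). These sizes
keep the whole suite comfortably under a minute of compute for the oracle
checks and a few seconds per simulated seed.

## Known limitations

* Co-occurrence is temporal association; nothing here supports claims of
  physical proximity or interaction.
* Plain Spearman on compositional data inherits closure-induced
  correlations (visible in the synthetic background component);
  compositionality-aware network methods are deliberately out of scope.
* The t approximation for Spearman p-values is asymptotic; for very short
  series (n < 10) an exact permutation test would be preferable.
* Connected components merge modules connected by even one spurious edge;
  the Louvain option mitigates this for dense graphs at the cost of
  determinism.
* NSAF comparisons across samples assume comparable acquisition depth;
  no batch correction is attempted.
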