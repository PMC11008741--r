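Package: bloomnet
Title: Cross-Kingdom Co-Occurrence Networks and Metaproteome
    Quantification for Phytoplankton Bloom Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing particle-associated microbiome time series
    from phytoplankton blooms: filtering and taxonomic roll-ups of 16S/18S
    rRNA gene amplicon count tables, cross-kingdom Spearman co-occurrence
    networks with Benjamini-Hochberg false discovery rate control and module
    extraction, normalized spectral abundance factor (NSAF) quantification of
    metaproteomes, linear-regression screens of lineage abundance against
    environmental covariates, and a seeded synthetic spring-bloom generator
    with planted community structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
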