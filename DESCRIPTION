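Package: exprbrowser
Title: Scriptable Browser for Replicated Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ingests wide-format replicated expression matrices (one row per
    gene, columns named <GROUP><replicate>) together with Gene Ontology
    annotation tables, precomputes a per-gene statistics lookup table (group
    means and standard errors, experiment-wide one-way ANOVA with
    Benjamini-Hochberg q-values, and Welch t tests with log2 fold changes for
    every pairwise group contrast), filters transcripts by symbol,
    description, GO term, expression level, fold change and q-value, and
    renders dot plots, volcano plots, gene-difference plots, heatmaps and
    principal component analyses, each paired with the exact data table
    plotted. Includes a seeded synthetic-data generator with known ground
    truth for power and false-discovery-rate evaluation, CSV/PNG export with
    Entrez Gene links, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
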