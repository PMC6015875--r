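Package: replimir
Title: miRNA Seed-Site Scanning and Small RNA-Seq Analysis of T-Cell Replicative Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking T-cell replicative age (cumulative
    population doublings) to miRNA-mediated regulation of CD28. Provides a
    seed-match scanner for the four canonical site classes (8mer, 7mer-m8,
    7mer-A1, 6mer) on 3'UTR sequences with reporter-construct seed
    mutagenesis design; CPM normalisation, detection filtering and exact
    Mann-Whitney differential expression for mature-miRNA count matrices;
    validation statistics (2^-dCt relative quantification, Spearman, exact
    Wilcoxon signed-rank, exact Friedman with baseline-anchored post hoc,
    paired t, dual-luciferase ratio normalisation); and a synthetic-data
    generator with ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
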