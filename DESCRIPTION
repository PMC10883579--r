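Package: endocycle
Title: Multilevel Simulation of Obligate Endosymbiosis with Boolean
    Cell-Cycle Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An agent-based evolutionary simulator of obligate endosymbiosis.
    Hosts and symbionts carry beads-on-a-string genomes (regulatory genes,
    binding sites, passive household genes) encoding stochastic Boolean
    gene-regulatory networks that drive a four-stage cell cycle (G1, S, G2, M)
    with replication-dependent gene dosage and a premature-mitosis death rule.
    Holobionts (one host plus one or more symbionts) live on a spatial grid
    with a nutrient gradient and share nutrients in their 3x3 neighbourhood.
    Host and symbiont regulatory systems interfere through passive product
    leakage, evolvable signal-peptide targeting, and endosymbiotic gene
    transfer at division. The package includes the full mutational operator
    set (duplication, deletion, relocation, innovation, per-bit and per-gene
    value mutations), an assay harness (clonal growth, interference knockouts,
    competition, ancestor-lineage reconstruction with Newick export), a
    line-based genome text format, and deterministic seeding with
    snapshot/restore of running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
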