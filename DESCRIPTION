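Package: organellr
Title: Reference-Free Plant Organellar Genome Assembly Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages for reference-free assembly of plant
    organellar genomes from PacBio HiFi reads: canonical k-mer read
    filtering, assembly-graph topology recognition with extraction of the
    two heteroplasmic chloroplast isomers, graph-alignment read refinement,
    and gene-panel completeness scoring. Also provides downstream analysis
    of nuclear insertions of organellar DNA (NUPTs and NUMTs): HSP
    filtering and merging, substitution spectra resolved by cytosine
    methylation context (CG, CHG, CHH), and permutation tests for small-RNA
    locus enrichment. Ships seeded synthetic-data generators (quadripartite
    chloroplast genomes, HiFi-like reads, planted nuclear insertions) so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
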