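Package: polydissect
Title: Dissection of Heterozygous Polyploid Genomes with a Collapsed Virtual Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting allopolyploid genomes by comparative sequence
    analysis. Provides a synthetic allo-octoploid genome and read simulator with
    per-base truth labels, k-mer spectrum genome-size estimation by coverage-peak
    selection, read and assembly quality control with contamination screening,
    construction of a heterozygosity-collapsed virtual reference genome by
    windowed overlap-layout-consensus, seed-and-extend local alignment with
    PSL-style records, best-hit selection, mapping-multiplicity and progenitor
    attribution, a microsatellite (SSR) census, and SSR allelic-peak
    phylogenetics with Jaccard distances, Ward clustering and multiscale
    bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
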