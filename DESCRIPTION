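Package: mgproteo
Title: Composition-Based Metagenome Binning and Censored Metaproteome
    Statistics for Microbial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing population genomes from assembled
    metagenome contigs of simple microbial consortia and for quantitative
    statistics on their label-free metaproteomes. Implements marker-seeded,
    two-round phylogenetic binning of contigs with an order-3 De Bruijn
    chain (tetranucleotide) composition signature, coverage-cluster
    extraction of genome reconstructions, weighted single-copy marker-gene
    completeness, best-hit average amino acid identity, reliability-scored
    greedy dereplication of protein databases at 95% identity, peptide to
    protein rollup, two-level median-of-ratios normalization, left-censored
    differential abundance tests with a power-law pooled variance, and
    Fisher/Benjamini-Hochberg pathway enrichment. Includes seeded synthetic
    community and proteome generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
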