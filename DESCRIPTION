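Package: breakgc
Title: Double-Strand-Break Repair and the Evolution of Prokaryotic GC Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking double-strand-break repair capacity
    (presence of the Ku/NHEJ machinery) to genomic GC content in prokaryotes.
    Implements polymorphism polarization in closely related genome triplets
    to estimate GC to AT mutational bias and equilibrium GC content, a
    pairwise homoplasy index (PHI) permutation test for recombination in gene
    alignments, restriction-site flank GC enrichment against a permuted-motif
    null with bootstrap confidence intervals, and maximum-likelihood
    phylogenetic regression of logit GC content on Ku presence and genome
    length under Brownian-motion or Ornstein-Uhlenbeck covariance with a
    measurement-error term. Seeded synthetic-data generators provide
    ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    nlme,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
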