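Package: GenomeEvoKit
Title: Comparative Genome Evolution: Gene-Content Phylogenetics, Macrosynteny
    and Neuropeptide Precursor Screening
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-genomic inference on whole-genome gene
    content and chromosome organisation. Implements maximum-likelihood and
    MCMC phylogenetics on binary gene presence/absence matrices under a
    time-reversible two-state model with ascertainment correction for
    unobservable (all-absent and singleton-presence) gene families; a
    reciprocal-best-hit orthology layer with Smith-Waterman scoring and
    orthogroup construction; ancestral-linkage-group (ALG) macrosynteny
    assignment by one-sided Fisher enrichment of shared orthologs with
    Benjamini-Hochberg control, including Oxford dotplot coordinates; a
    dibasic-repeat neuropeptide precursor screen with length and
    E-value-ratio validation; and a genome-evolution simulator (gene
    gain/loss on trees, divergent protein sequences, ALG-structured
    karyotypes with fusion/fission histories, planted precursors) that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ape,
    phangorn,
    igraph,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
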