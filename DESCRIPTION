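Package: KmerPhylo
Title: Alignment-Free Phylogenetics from k-mer Frequency Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds k-mer frequency profiles directly from FASTQ reads,
    computes pairwise Jensen-Shannon and Hellinger divergences between
    samples, infers unrooted neighbor-joining trees and classical
    multidimensional-scaling embeddings, and compares trees by the
    Robinson-Foulds symmetric distance and the Kuhner-Felsenstein
    branch-score distance. Aimed at longitudinal and multi-region tumor
    sequencing cohorts, where whole-sample divergence profiles recover
    clonal structure without alignment or variant calling. Includes a
    clonal-evolution read simulator with a known truth tree for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
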