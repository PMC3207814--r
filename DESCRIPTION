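Package: tagdex
Title: Cross-Species Differential Expression from 3' Tag Sequencing Without a Reference Genome
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-genome-free differential expression between a focal
    species quantified on de novo transcriptome contigs and an annotated
    reference species, using 3' tag digital gene expression libraries.
    Provides a seeded synthetic-data generator with full ground truth
    (orthology structure, contig coverage, 3'-biased tag reads, poly-A/T
    artifacts), tag read placement with a 3'-window retention rule,
    dual-reference contig-to-ortholog disambiguation by e-value clearance,
    a pseudocount-corrected fold-difference statistic with a log-ratio
    normalization diagnostic, hypergeometric over-representation analysis
    with Benjamini-Hochberg adjustment, and qPCR standard-curve / delta-Ct
    relative quantification arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
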