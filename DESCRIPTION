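Package: phasebench
Title: Alignment-Based Benchmarking of Phased Small Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks locally phased small variant callsets (SNPs and
    INDELs under 50 bp) against a phased truth set using affine-gap
    realignment rather than exact record matching. Query and truth VCFs are
    decomposed, trimmed and re-expressed in a standard representation by
    realigning each cluster of dependent variants under a fixed affine-gap
    penalty scheme; truth and query clusters are grouped into independent
    superclusters, evaluated with local-phasing-aware alignment against a
    variant-aware query graph, and scored with fractional (partial) credit
    for mostly-correct calls. Reports precision/recall and F1 Q-scores over
    quality thresholds, sequence distance metrics (edit distance, distinct
    edits, alignment distance) and their Q-scores, switch errors recovered
    by a phase-block dynamic program, and representation-stability
    statistics (average maximum rank change and R-squared across
    representations). Includes a deterministic synthetic data generator
    producing reference contigs, diploid truth haplotypes and equivalent
    query representations with planted errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    jsonlite,
    generics,
    vcfR,
    Biostrings,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
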