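Package: ltrscout
Title: Signature-Based Detection of LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("ltrscout", "developers", email = "ltrscout@example.org",
           role = c("aut", "cre"))
Description: Detects long terminal repeat (LTR) retrotransposons in genome
    assemblies from their structural signature alone. Each sequence is scored
    by bidirectional k-mer match distances, runs of similar scores are merged
    into stretches by a statistical procedure and assembled into candidate
    LTRs by a trained linear classifier, candidates are paired in a
    directed-weighted graph that resolves single elements, solo LTRs,
    recently nested, sequential, and deeply nested insertions, and surviving
    elements are confirmed by structural filters (polypurine tract, terminal
    inverted repeat decoys, target site duplications). Includes a synthetic
    plant-genome simulator with exact truth annotations, a repeat-content
    profiler, alignment-based identity scoring, and a reciprocal-overlap
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
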