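Package: tiscall
Title: Prediction of Non-Canonical Translation Initiation Sites in mRNA 5' UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates AUG and near-cognate candidate translation initiation
    sites in annotated 5' UTRs, computes 1,252 sequence-derived features
    (position weight matrices, Kozak context, flanking-context translational
    efficiency, secondary-structure and GC windows, human-ortholog
    conservation, and a position-specific and 3-mer k-mer search), trains
    linear and support-vector regression models that map candidates to a 0-1
    initiation confidence, and performs in-silico single-nucleotide
    mutagenesis of start-site flanking contexts. Includes a synthetic-data
    generator emulating ribosome-profiling-derived start-site tables so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
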