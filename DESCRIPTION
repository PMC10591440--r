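Package: paleosift
Title: Screening and Authentication of Ancient Metagenomic Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and authenticating microbial taxa in
    ancient metagenomic sequencing data. Implements depth and breadth of
    coverage filtering of KrakenUniq-style classifier reports, unique
    k-mer accounting that grounds the breadth-of-coverage proxy,
    alignment-based validation metrics (deamination profiles, edit
    distance, read length, percent identity, post-mortem damage scores,
    binned evenness of coverage), a 0-10 authentication scoring system,
    detection benchmarking (Jaccard, F1, ROC), and a Briggs-model
    simulator of damaged, fragmented ancient reads with ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    ggplot2,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
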