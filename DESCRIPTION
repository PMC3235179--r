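Package: probekit
Title: Probe Design and Expression Analysis for Two-Color Transcriptome
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating whole-transcriptome
    two-color oligonucleotide microarrays. Designs 60-mer probes from a
    transcript FASTA under GC, melting-temperature, homopolymer and 3'-bias
    constraints; classifies probe specificity against any annotation release
    by exhaustive bounded-mismatch search (single/multiple/none calls);
    simulates two-channel hybridizations with probe affinity effects,
    intensity-dependent dye bias and lognormal background; and analyses
    intensities through background detection, MA computation, lowess
    normalization, per-transcript testing with Holm-Bonferroni correction,
    two-fold differential-expression calling, Ward clustering, cross-platform
    concordance and knockout detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
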