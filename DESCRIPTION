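Package: txerror
Title: Transcription Error Rates from Rolling-Circle Consensus Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates transcriptome-wide transcription error rates from
    rolling-circle (circularized-cDNA) sequencing libraries, in which each
    read carries several tandem copies of one mRNA fragment so that true
    transcription errors (present in every copy) can be separated from
    library and sequencing artifacts (present in a single copy). Provides a
    synthetic-data generator that emulates the library chemistry with known
    injected errors, tandem-repeat consensus calling with a quality cutoff
    and unanimity rule, per-substitution-type error rates with base
    composition normalization, RNA:DNA-hybrid sequence-context analysis
    with Monte Carlo background normalization, and the exact small-sample
    statistics (Mann-Whitney U, Fisher's exact test, Benjamini-Hochberg
    FDR) used to compare factorial fidelity-factor knockout designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
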