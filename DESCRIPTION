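Package: damidcompare
Title: Comparative DamID-Seq Analysis of Transcription-Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for comparative DamID-seq analysis of
    transcription-factor binding across related genomes. Builds the GATC
    fragment partition of a genome, quantifies extended-read coverage per
    fragment, calls binding intervals by negative-binomial differential
    enrichment of fusion versus Dam-only samples, translates intervals and
    reads between species through UCSC chain alignments with a minimum-match
    filter, classifies cross-species binding conservation and compensatory
    turnover, performs jointly normalized quantitative binding comparisons
    (affinity scores, correlation clustering, PCA, differential binding),
    scores motif conservation in multiple alignments with exact PWM score
    p-values, and simulates multi-species genomes with planted binding sites
    and replicate DamID read sets for validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
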