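Package: wgdclock
Title: Dating Whole-Genome Duplications and Retrotransposon Insertions
    from Synonymous-Substitution Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparative-genome molecular-clock
    analyses: pairwise Ka/Ks estimation by the Nei-Gojobori (1986)
    counting method, block-median Ks distributions from syntenic
    collinearity anchors, Gaussian-mixture peak detection with bootstrap
    uncertainties, cross-species evolutionary-rate correction and
    absolute dating of polyploidy events against a hexaploidy
    calibration, LTR retrotransposon insertion-time estimation from
    5'/3' LTR divergence, per-GO-category binomial tests for
    lineage-accelerated protein evolution, and intact-versus-fragmentary
    transposable-element proximity-to-gene analysis. A seeded synthetic
    data generator emulates every input so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    optparse
Config/testthat/edition: 3
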