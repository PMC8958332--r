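Package: pcunet
Title: Protein-Coding Units as Bayesian Networks from Multi-Omics Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents the multi-omics protein-coding unit of a gene --
    chromatin-accessibility peaks, transcript isoforms and the protein --
    as a three-layer Bayesian network, enumerates the conditional
    independencies (Markov conditions) implied by each network, and
    verifies them empirically from replicated time-series data using
    dynamical correlations, partial correlations and a Fisher z
    threshold. Includes construction of the networks from peak/transcript
    association tables or genomic coordinates, joint networks for shared
    peaks and protein complexes, dominant splice-variant inference,
    null-model benchmarks, structural balance and inverse balance
    (signed MTP2) classification of signed correlation graphs,
    ROC/precision-recall threshold sweeps, and a synthetic-data generator
    with controllable planted violations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
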