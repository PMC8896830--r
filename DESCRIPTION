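Package: epicoloc
Title: Genome-Wide Co-Localization Analysis of 5hmC and R-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for testing genome-wide
    co-localization of epigenomic marks such as 5-hydroxymethylcytosine
    (hMeDIP-seq peaks) and R-loops (DRIP-seq regions) at active genes.
    Builds one merged transcript model per gene from GTF annotations,
    filters to transcriptionally active genes by a TPM percentile,
    assigns peaks to flanked gene windows, computes binned RPKM coverage
    tracks with 3'-extended reads, summit-anchored metaprofiles and
    gene-body-scaled metagenes, a count- and length-preserving
    interval-shuffle permutation test with an empirical p-value,
    per-gene mark classification and binned-signal correlation,
    transcription-readthrough quantification downstream of the TTS with
    a Mann-Whitney two-condition comparison, and Fisher's-exact pathway
    enrichment of dual-marked differentially expressed genes with
    Benjamini-Hochberg control. Includes a synthetic-data generator
    with planted co-occurrence and readthrough structure for
    recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
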