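Package: cobindseq
Title: Consensus ChIP-Seq Binding Sites, Co-Occupancy Classification and
    Composite Motif Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor binding sites supported by multiple
    peak callers, scores them against an IgG control with a negative-binomial
    background model, classifies two-factor co-binding patterns by K-means
    clustering of z-scored coverage profiles, scans binding-site sequences for
    degenerate composite motifs with a variable-length spacer (such as the
    E-box/GATA signature CTG-N(6-8)-WGATAR), and annotates sites by nearest
    transcription start site. Ships a fully ground-truthed synthetic-data
    generator so every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    Biostrings
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
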