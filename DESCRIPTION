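Package: gingerscan
Title: Structural Annotation of Gypsy-Integrase DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery, structural annotation and classification of cut-and-paste
    DNA transposons that encode Gypsy-integrase-like transposases (the Ginger1 and
    Ginger2/Tdd groups). Provides a seeded synthetic-genome generator that plants
    TIR-flanked elements with 4-bp target site duplications, TGTNR termini and
    intron-bearing transposase genes; six-frame translation and Smith-Waterman
    homology scanning; terminal-inverted-repeat and target-site-duplication
    detection with boundary refinement; family clustering, consensus rebuilding and
    copy-divergence statistics; homology-guided spliced gene models with intron
    phases and protein motif scanning (YPYY, H2C2 zinc finger, DDE triad, GPY/F,
    OTU/Ulp1/PHD tails); rule-based element classification; TSD sequence-logo
    statistics; and distance phylogenetics (Poisson/gamma corrections, pairwise
    deletion, neighbor-joining and minimum-evolution trees with bootstrap support).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    GenomicRanges,
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
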