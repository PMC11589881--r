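Package: ctails
Title: C-Terminal Transmembrane Helix Topology, Hydrophilicity and
    Insertion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the C-terminal transmembrane helices (cTMs)
    of multispanning membrane proteins: merging topology predictions from
    several predictors into a quality-labelled consensus, scoring loops and
    C-terminal tails with the biological hydrophobicity scale (apparent
    insertion free energy), classifying proteins by C-terminal orientation
    (cytosolic versus extracytosolic) and insertion route (co- versus
    post-translational, 45-residue rule), analysing stop-loss (nonstop)
    variants that extend the C-tail to the next in-frame stop codon with a
    misinsertion prediction, comparing groups with a two-sided Mann-Whitney
    test, and quantifying membrane insertion from cysteine-accessibility
    PEGylation densitometry. Includes seeded generators of synthetic
    proteomes, predictor outputs, coding sequences and gel quantifications
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
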