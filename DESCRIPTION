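Package: dppsubs
Title: Dipeptidyl Peptidase Substrate Discovery from TAILS N-Terminomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for discovering in vivo substrates of dipeptidyl
    peptidases (DPPIV/S9b family) from TAILS N-terminome experiments. Annotates
    expected mature protein N-termini (initiator-Met excision, signal-peptide
    removal), enumerates semi-specific digestion peptides, classifies peptides as
    N-terminal substrates or dipeptidyl cleavage products, normalizes and imputes
    TMT reporter matrices, pairs substrate and product peptides by fold-change
    geometry, annotates P2/P1/P1' residues around the scissile bond, fits an
    S0-moderated permutation-FDR enrichment statistic for IP-MS protein-group
    tables, summarizes in vitro cleavage time courses, and simulates complete
    synthetic experiments with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
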