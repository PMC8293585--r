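Package: evlink
Title: Linking Extracellular Vesicle miRNA Cargo to Recipient-Cell Gene Repression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling microRNAs specific to one source of
    extracellular vesicles (EVs) from replicated small-RNA count libraries,
    mapping their high-confidence predicted targets into a recipient-cell
    differential-expression table, and testing whether EV miRNA abundance
    predicts the repression of downregulated targets via a weighted Pearson
    correlation, with detection-threshold sweeps, cutoff sensitivity grids,
    and a negative-binomial synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
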