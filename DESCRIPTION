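Package: tcrcyto
Title: Integrated T-Cell Receptor Repertoire and Cytokine Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking multiplex cytokine panels with
    T-cell receptor (TCR) beta-chain repertoires profiled in paired
    cerebrospinal fluid (CSF) and blood samples. Reads immunoSEQ-style
    rearrangement tables and 48-analyte cytokine panels; preprocesses
    concentrations (IQR outlier screening, log2(x+1), Winsorization) and builds
    FDR-thresholded Pearson correlation networks; computes clone-sharing and
    repertoire statistics (Simpson clonality, TRBV usage, clone taxonomy);
    identifies potentially relevant CDR3 amino-acid sequences from CSF and
    clusters their rank profiles against a healthy reference cohort; and
    associates disease-predominant sequences with cytokine levels via
    tie-corrected Kendall correlation with Benjamini-Hochberg control. Ships a
    synthetic-cohort generator with planted, recoverable structure so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
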