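Package: screenRRA
Title: Analysis of Pooled CRISPR/Cas9 Knockout Screens with Robust Rank
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies positively and negatively selected sgRNAs, genes and
    pathways from genome-scale pooled CRISPR/Cas9 knockout screens.  Read
    counts are median-ratio normalized, per-sgRNA significance is assessed
    with a negative binomial test whose variance is borrowed across sgRNAs
    through an empirical mean-variance regression, and gene- and
    pathway-level selection is scored by alpha-restricted robust rank
    aggregation (alpha-RRA) with permutation-based false discovery rates.
    Includes a synthetic-screen simulator for calibration and power studies
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
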