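Package: panelqc
Title: Quality Control for Targeted RNA Expression Panels with Control Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-level quality control for targeted RNA expression panels
    (HTG EdgeSeq-style instruments) that carry positive spike-in and negative
    non-human control probes. Computes per-sample control-read fractions,
    counts-per-million (CPM) deviance of the negative controls with a +/- k
    standard-deviation band, and a two-filter PASS/ALERT/FAIL flag scheme.
    Includes CPM, log2-CPM and a closed-form negative-binomial variance
    stabilizing transformation, QC-aware principal component analysis and
    hierarchical-clustering heatmap exports, a synthetic-run generator with
    known ground-truth flags, and a command-line interface.
License: MIT + file LICENSE
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
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
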