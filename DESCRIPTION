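Package: qhtscreen
Title: Quantitative High-Throughput Screen Triage for Organoid Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for quantitative high-throughput phenotypic screens run
    on dissociated retinal organoids in 1536-well plates: plate and layout
    input/output, automated quality-control masking of localized well
    artifacts, intra-plate percent normalization of a GFP reporter channel
    (efficacy), a DAPI viability channel (toxicity) and a GFP-negative
    counter-screen channel (compound autofluorescence), four-parameter Hill
    concentration-response fitting with multistart bounded least squares,
    qualitative curve classification, and selectivity-ratio hit triage. A
    ground-truth-labelled synthetic screen generator emulates the disease
    phenotype (reduced viability and reporter-positive cell fraction), plate
    gradients and lognormal well noise so the whole funnel is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
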