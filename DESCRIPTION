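Package: pgsa
Title: Pyramid Gravitational Search for Gene Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper gene selection for multi-class expression data by a
    pyramid gravitational search algorithm: genes are first ranked by
    Shannon entropy, then an improved binary gravitational search
    optimizer, scored by the held-out accuracy of a polynomial-kernel
    support vector machine, cyclically shrinks the gene pool. Includes
    per-class evaluation metrics with a cross-validated kernel sweep, a
    synthetic expression-data generator with planted informative genes,
    delimited-matrix readers and writers, and tidy()/glance()/autoplot()
    methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
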