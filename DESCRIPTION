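Package: coalpsi
Title: Coalescent Theory and Estimation of the Psi Directionality Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form coalescent expectations, variances and shared-SNP
    counts for the psi directionality index in two-population demographies
    (population split, exponential growth, prolonged bottleneck, and
    instantaneous founder bottleneck), together with a structured-coalescent
    Monte Carlo simulator for samples of two lineages per population, a
    synthetic sequence-alignment generator under infinitely-many-sites
    mutation, and the empirical psi estimation pipeline: outgroup
    polarization, site filtering, quartet resampling and locus bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
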