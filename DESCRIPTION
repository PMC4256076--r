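Package: dyver
Title: Dynamic Genetic Effects on Time-Course Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Maps genetic variants that control time-series gene expression
    in panels of homozygous inbred strains, and classifies when each variant
    acts. Expression differences between strains carrying opposite alleles
    ("observed effects") are modelled with a two-state Gaussian-emission
    hidden Markov model over time points; a likelihood-ratio statistic (the
    DyVER score) contrasts cross-allele and same-allele differences, with
    significance assessed by strain-label permutation. Includes the
    companion synthetic-data generators (sustained, impulse, complex and
    linear temporal effect waveforms plus Markov-sampled state paths),
    baseline mapping methods (per-time-point ANOVA, PCA projection,
    expression-dynamics covariate models), variant-aware accuracy metrics,
    and post-scan cataloguing of temporal effect patterns and
    co-association modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
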