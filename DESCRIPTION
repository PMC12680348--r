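Package: strsel
Title: Selection Inference at Short Tandem Repeats from Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward population-genetic simulation of short-tandem-repeat (STR)
    allele-frequency evolution under a generalized stepwise mutation model with
    length-dependent rates and directional bias, linear selection around an
    optimal allele length, and multi-epoch demography with genetic drift.
    An approximate Bayesian computation (ABC) layer jointly infers a gamma
    distribution of selection coefficients (the distribution of fitness
    effects, DFE) across sets of STR loci from their heterozygosity
    distributions, selects among candidate mutation-rate models for putatively
    neutral loci, and converts inferred DFEs into per-genome fitness-burden
    estimates for de novo and inherited STR variation, with closed-form
    single-nucleotide-variant comparisons. Includes a synthetic-data generator
    that produces allele-frequency tables with known ground truth by running
    the simulator itself.
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
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
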