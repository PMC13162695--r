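Package: coalscan
Title: Coalescent Simulation, SFS-Based Demographic Model Choice, and
    Genome Scans for Introgression and Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing competing demographic origin scenarios of
    structured populations with the multidimensional site frequency
    spectrum (SFS). Provides a seeded structured-coalescent simulator with
    population splits, bottlenecks and admixture pulses; SFS construction
    with outgroup polarization, site filtering, folding and hypergeometric
    projection; composite-likelihood fitting of parametrized demographic
    models by Monte-Carlo expected spectra with multi-run optimization,
    delta-likelihood and AIC model comparison and parametric bootstrap
    intervals; allele-frequency introgression statistics (ABBA-BABA D with
    block-jackknife Z scores, outgroup f3, sliding-window fd, topology
    weighting on genealogies); and a three-statistic selective-sweep scan
    (windowed Weir-Cockerham Fst, nucleotide diversity ratio, XP-EHH) with
    top-quantile intersection and region-to-gene mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
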