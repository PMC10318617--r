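Package: imcoal
Title: Isolation-with-Migration Coalescent Simulation and Demographic
    Posterior Analysis for Multilocus RAD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mutation-scaled isolation-with-migration demographic
    models of structured populations: a structured-coalescent simulator with
    divergence and directional migration bands producing RAD-like multilocus
    datasets (infinite-sites mutations, diploid individuals, whole-locus
    missingness, minimal VCF export); joint two-population site frequency
    spectra with weighted F_ST (Hudson and Reynolds ratio-of-sums estimators)
    and Slatkin linearization; diversity and divergence statistics with
    moment-based parameter recovery; individual genetic distance matrices and
    Mantel isolation-by-distance tests; post-processing of mutation-scaled
    coalescent MCMC traces (burn-in, highest posterior density intervals,
    effective sample sizes, Monte-Carlo conversion to absolute effective
    population sizes, divergence times in years and population migration
    rates, migration-band significance screening); and the genealogical
    divergence index with species-delimitation classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    vcfR,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
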