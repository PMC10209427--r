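Package: coregonid
Title: Integrative Species Delimitation for Coregonid Whitefish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative taxonomic delimitation of lake whitefish
    (Coregonus) species flocks. Implements multivariate ratio analysis of
    morphometric characters (two-group linear discriminant analysis in log
    space, exhaustive best-ratio extraction by standard distance, and a
    delta statistic quantifying the allometric content of a discriminant),
    diagnostic-ratio overlap screening, dichotomous identification-key
    evaluation, meristic frequency-table diagnostics, microsatellite
    population genetics (Weir-Cockerham theta with permutation tests,
    Hardy-Weinberg permutation tests, Cavalli-Sforza chord distances,
    neighbour-joining with locus bootstrap, and the Evanno delta-K cluster
    number criterion fed by an EM mixture surrogate for Bayesian
    clustering), constant-rate sediment-core chronology, and synthetic-data
    generators for allometric morphometrics, discretized meristic counts
    and island-model microsatellite genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
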