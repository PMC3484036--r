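Package: fluxscape
Title: Multi-Goal Metabolic Engineering Design over Constraint-Based Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration and screening of metabolic engineering
    designs (medium composition by gene-deletion genotype) over
    constraint-based metabolic models. Solves flux balance analysis linear
    programs for every design, computes a 36-trait engineering phenotype
    vector per viable design (production rates, purities, carbon yields,
    and economic cost, revenue and profit rates), classifies phenotypes
    into meta-phenotypes by k-means clustering with gap-statistic model
    selection, extracts Pareto-optimal designs and piecewise-linear
    tradeoff slopes for arbitrary goal combinations, and builds
    perturbation-typed meta-phenotype transition networks. Includes an
    expression-to-flux consistency score (GIMME-style) and a synthetic
    fixture generator producing small carbon-balanced toy models with
    closed-form maximum yields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
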