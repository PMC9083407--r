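Package: wildgut
Title: Longitudinal Analysis of Wild-Rodent Gut Microbiota Dynamics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal 16S amplicon studies of wild animal
    populations sampled by capture-mark-recapture. Provides a
    SummarizedExperiment-based container for ASV count tables with host
    metadata and taxonomy; sample- and taxon-level filtering (organelle
    removal, sequencing-depth and prevalence filters); Bray-Curtis and
    Jaccard dissimilarities with principal coordinates analysis; core-taxon
    delimitation from subsampled prevalence, within-individual persistence
    and joint prevalence-abundance thresholds; cross-population taxon
    sharing with bootstrap controls; permutational rank tests for host
    individuality, time-decay of community similarity, and seasonal
    convergence; harmonic (cyclic) regression for day-of-year effects;
    and a permutational multivariate ANOVA with multivariate dispersion
    tests. A Dirichlet-multinomial simulator with known individual,
    seasonal and population structure supplies ground-truth data for
    validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    biomformat,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
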