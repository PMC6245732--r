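Package: alleleKinetics
Title: Stochastic Models of Mono- and Bi-Allelic Gene Activation Kinetics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hidden-state continuous-time Markov models of allele-specific
    gene activation in proliferating cell populations, with tools to quantify
    non-, mono-, and bi-allelically expressing population fractions from
    two-channel single-cell fluorescence data by constrained four-component
    bivariate Gaussian mixture fitting, fit candidate activation models
    (cis-only, sequential trans-cis, parallel trans-cis) with per-class
    detection-delay correction and compare them by reduced chi-squared and
    F-test, simulate clonal lineage trees by Monte-Carlo and classify clones
    by their allelic expression pattern, and map perturbation responses in
    the (mono-allelic, bi-allelic) population phase space. Includes a
    synthetic timelapse/snapshot data generator emulating the statistical
    structure of dual-reporter imaging experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    digest,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, CellBiology, GeneExpression, TimeCourse,
    MathematicalBiology, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cloneSim.R'
    'io.R'
    'mixtureQuantify.R'
    'modelFit.R'
    'perturbationPhase.R'
    'pipeline.R'
    'plotMethods.R'
    'stateModels.R'
    'syntheticData.R'
    'utils.R'
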