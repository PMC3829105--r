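Package: fluxrecon
Title: Reconciling Chemostat Growth Measurements with Constraint-Based
    Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconciling steady-state chemostat measurements with
    genome-scale constraint-based metabolic models of bacteria such as
    Pseudomonas putida KT2440. Implements growth-parameter estimation
    (OD-to-dry-weight calibration, Pirt regression for the maximal biomass
    yield and maintenance coefficient, washout fitting of the maximal growth
    rate, carbon and nitrogen balancing), construction of a normalized
    biomass objective function from macromolecular composition and monomer
    tables, fitting of growth-associated and non-growth-associated ATP
    maintenance (GAM/NGAM), flux balance and flux variability analysis by
    linear optimization, comparison of flux intervals against 13C-derived
    flux measurements via the FVA-distance statistic, and
    transcriptomics-model consistency checks. Includes seeded synthetic-data
    generators (chemostat, washout, toy central-carbon network, measured
    fluxes, expression arrays) and an end-to-end reconciliation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    xml2,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SystemsBiology, Metabolomics, Transcriptomics, Software
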