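Package: comparonc
Title: Comparative Cancer Mortality Risk from Managed-Population Animal Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species-level cancer mortality risk from
    individual-level records of managed (zoo) mammal populations and tests
    its life-history correlates on a phylogeny. Builds adult cohorts with
    left truncation at a study window, fits delayed-entry Kaplan-Meier
    survival curves and adult life expectancies, and computes two risk
    metrics: the crude cancer mortality risk (CMR, cancer deaths over
    necropsied individuals) and the competing-risks cumulative incidence of
    cancer mortality (ICM, the sum over cancer event ages of survival times
    the cause-specific hazard jump). Species-level analyses include Pagel's
    lambda phylogenetic signal, lambda-profiled generalized least squares,
    penalized quasi-likelihood phylogenetic logistic regression, a
    zero-inflated two-part model of risk against body mass and adult life
    expectancy, prediction-based partial coefficients of determination,
    phylogenetic paired t-tests for sex bias, per-food-item diet models and
    taxonomic-order contrasts. A synthetic-data generator produces
    phylogenies, species traits and individual records with known ground
    truth so the whole inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    phytools,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
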