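Package: massresponse
Title: Functional Drug-Response Testing from Single-Cell Buoyant Mass Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for calling cancer drug response from
    single-cell buoyant mass measurements, such as those produced by suspended
    microchannel resonator (SMR) instruments. The treated-versus-vehicle
    difference of mass distributions is quantified as a normalized Earth
    Mover's Distance ("mass response"), tested against a non-zero limit of
    decision with an embedded bootstrap-t procedure, and reported with
    bias-corrected and accelerated (BCa) bootstrap confidence intervals.
    Includes particle-class curation of measurements (intact and permeable
    cells versus aggregates and debris), a synthetic-experiment simulator for
    baseline noise, mechanism-of-action effects, responding-fraction mixtures
    and phenotypic drift, and a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
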