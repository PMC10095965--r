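Package: gravibend
Title: Growing Elastic-Rod Mechanics of Shoot Gravitropism
Version: 0.1.0
Authors@R:
    person("gravibend", "maintainers", email = "maintainers@gravibend.org",
           role = c("aut", "cre"))
Description: Tools for analysing shoot gravitropism as the interplay of
    growth, gravi-proprioceptive curvature dynamics and rod elasticity.
    The package simulates a growing discrete elastic rod clamped at its
    base and relaxed to mechanical equilibrium under stretching, bending
    and gravitational forces; updates the intrinsic curvature of the
    apical growing zone by a gravitropic sine law opposed by
    proprioceptive straightening; extracts curvature kymographs,
    extension ratios and maximum curvatures from sampled centerlines via
    spline fits; fits the two governing dimensionless parameters (the
    growth-sensitivity number S and the growth-elasto-gravity number G)
    to morphospace coordinates by exhaustive grid search; decomposes
    shoot motion into per-force displacement fields; and maps
    differential flank growth (DCG). A synthetic-data generator produces
    ground-truth-known time-lapse cohorts emulating near-horizontal
    Arabidopsis inflorescence stems so that every stage is testable
    without experimental images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
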