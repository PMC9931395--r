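Package: gratiomap
Title: Myelin-Sensitive MRI Measures and Aggregate g-Ratio Mapping
Version: 0.1.0
Authors@R:
    person("gratiomap", "developers", email = "gratiomap@example.org",
           role = c("aut", "cre"))
Description: Tools to compare myelin-sensitive quantitative MRI measures and
    the aggregate g-ratio maps derived from them. Implements myelin water
    fraction (MWF) estimation from multi-echo spin-echo data by regularized
    non-negative least squares with extended-phase-graph stimulated-echo
    correction and by a sparsity-promoting joint NNLS (SPIJN) algorithm;
    inhomogeneous magnetization transfer ratio (ihMTR), MT saturation
    (MTsat), calibrated proton density and macromolecular tissue volume
    (MTV) mapping; conversion of each measure to a myelin volume fraction,
    splenium-based calibration of linear scalings, axonal volume fractions
    from NODDI signal fractions, and voxelwise g-ratio maps. A synthetic
    brain-phantom cohort generator (healthy and lesioned subjects with
    ground truth) makes the whole pipeline testable end to end, and a VOI
    statistics layer reproduces lesion/perilesion morphology and the
    cohort-level summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
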