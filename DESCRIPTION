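Package: usemr
Title: Unified Structural Equation Models for Directed Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the unified structural equation model (uSEM) family of
    structural vector autoregressions to multivariate region-of-interest
    (ROI) time series: data-driven and confirmatory uSEM, the extended
    uSEM (euSEM) with direct and bilinear effects of a task input
    convolved with a double-gamma hemodynamic response function, and the
    two-stage group iterative multiple model estimation (GIMME) search.
    Estimation is maximum likelihood on block-Toeplitz lagged covariance
    matrices, with modification-index (Lagrange multiplier) driven model
    search and Wald trimming.  Includes a posteriori validation of the
    temporal order of fitted maps: white-noise testing of one-step-ahead
    prediction errors against a lag-3 vector autoregression null, and
    decision criteria that escalate maps to higher lag orders until the
    residuals are white.  A simulator for single-subject and
    group-structured ROI series supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
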