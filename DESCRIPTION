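Package: oarvar
Title: Interobserver Variability Analysis for Organ-at-Risk Delineations
Version: 0.1.0
Authors@R:
    person("OAR", "Variability Maintainers", email = "maintainers@oarvar.org",
           role = c("aut", "cre"))
Description: Quantifies interobserver variability of manually delineated
    organ-at-risk structures on axial CT. Provides a planar-contour data
    model with a canonical JSON interchange format and a read-only DICOM
    RT Structure Set adapter, grid-free slab volumes and even-odd
    rasterization to binary masks, volume descriptives (mean, SE, CV,
    per-observer OAR ratio, tie-corrected Friedman test), a three-way
    mixed-effects variance-component intraclass correlation coefficient
    with agreement bands, the pairwise concordance index (Jaccard overlap),
    and a median contour surface with per-vertex and per-region 3D
    standard deviations of signed observer distances. A synthetic
    multi-observer cohort generator with known ground truth makes every
    stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
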