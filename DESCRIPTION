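Package: gwrkit
Title: Hounsfield Unit and Gray-White Matter Ratio Analysis for Pediatric Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying regional brain attenuation (Hounsfield
    units) on axial head CT slices and for computing gray-white matter
    ratios (GWR) with the twelve formulas in common clinical use.
    Measurements are taken either over full segmented regions of interest
    (ROI) or within small circular probes (DOT method), with bilateral
    averaging. The package quantifies ROI-vs-DOT agreement (Bland-Altman
    limits of agreement, intraclass correlation), produces age-stratified
    normative summaries with normality-gated two-group tests and
    Bonferroni correction, and fits power-law and linear age-response
    curves. A seeded synthetic-cohort module generates age-parameterized
    two-slice brain phantoms (HU image plus co-registered integer label
    map, NIfTI interchange) so the full pipeline is testable without
    access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
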