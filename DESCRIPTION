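Package: glymclust
Title: Cluster Analysis of CSF Tracer Transport Kinetics from Dynamic
    Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the transport of cerebrospinal-fluid (CSF)
    tracers through the mouse glymphatic system with dynamic
    contrast-enhanced MRI. Extracts region-of-interest (ROI) time courses
    from 4D image series, performs baseline subtraction and input-function
    normalization, computes pairwise time-lagged cross-correlation (maximal
    cross-correlation coefficient and lag-time matrices), and clusters ROIs
    by complete-linkage hierarchical clustering on the 1 - mCC dissimilarity
    with multiscale-bootstrap AU/BP cluster probabilities. Ships a synthetic
    phantom generator with known transport lags and cluster structure for
    validation, and NIfTI/TSV/JSON/Newick input-output for every stage.
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
    RNifti,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
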