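Package: gelwarp
Title: Band Straightening for Isoelectric-Focusing Gel Lanes by
    Correlation-Optimized Hierarchical Warping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for removing uniform and non-uniform vertical band
    distortions from scanned isoelectric-focusing (IEF) gel lane images,
    as used in oligoclonal-band analysis of cerebrospinal fluid, serum and
    tear samples. Provides lane rectification from segmented edge contours,
    rolling-ellipsoid morphological background removal, an
    energy-minimizing correlation-based hierarchical warping algorithm with
    a strain regularizer and a zero-mean-shift-per-row constraint, an
    annotation-driven tracing-assistant warp, a synthetic lane simulator
    with ground-truth deformation fields, and a standard-deviation based
    evaluation protocol (per-band SD, threshold counts and their ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
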