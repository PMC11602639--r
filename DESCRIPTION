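Package: fatnavr
Title: Rigid Registration and Motion Quantification for 3D Fat-Navigator MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for navigator-based prospective motion correction in brain
    MRI. Provides a rigid 3D registration algorithm driven by the concordance
    correlation coefficient (CCC) with sub-volume selection and sequential
    per-axis search, the SSIM and RMSE similarity metrics for comparison,
    rigid-body transform algebra with Tisdall-style motion scores (worst-case
    displacement on a 64 mm sphere plus translation norm) and residual motion
    scores against ground truth, a synthetic fat-navigator phantom generator
    with a randomized rigid-transform benchmark protocol, image-sharpness
    metrics (variance of the Laplacian, edge-profile 75-to-25 percent width),
    and a measurement-level simulator of the prospective correction loop with
    alternating corrected and uncorrected measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
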