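Package: potholes
Title: Pothole and Molehill Cluster Analysis of White-Matter Fractional
    Anisotropy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects spatially independent clusters of abnormally low
    ("potholes") or high ("molehills") fractional anisotropy in cohorts of
    spatially aligned diffusion-MRI FA volumes. Builds voxel-wise cohort
    reference mean/SD images and per-subject z-maps over a white-matter mask,
    labels contiguous suprathreshold clusters at multiple volume thresholds,
    assigns clusters to labeled white-matter tracts, computes a p-value
    thresholded additive polygenic risk score, and runs the FDR-corrected
    linear-regression association suite relating cluster counts to age, sex
    and genetic risk. Ships a synthetic-cohort generator with planted
    ground-truth anomalies and a score-linked anomaly rate so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
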