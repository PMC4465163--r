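Package: pettex
Title: Textural Analysis of FDG-PET Tumor Volumes for Outcome Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intratumoral heterogeneity analysis of FDG-PET volumes
    in standardized uptake value (SUV) units. Segments tumor volumes of
    interest as SUV isocontours around the hottest voxel, computes
    conventional PET metrics (SUVmax, SUVmean, metabolic tumor volume,
    coefficient of variation) and 3D textural features from 64-bin
    discretized SUV data via gray-level co-occurrence matrices (13
    directions) and neighborhood gray-tone difference matrices (entropy,
    correlation, contrast, coarseness, busyness). Associates features with
    recurrence and survival endpoints through ROC analysis with
    distance-to-corner optimal cutoffs, Kaplan-Meier/log-rank comparisons
    and Cox proportional-hazards regression, and quantifies feature
    stability across isocontour thresholds and dependency on tumor volume.
    Includes a synthetic phantom-and-cohort generator (Gaussian random
    field tumors with proportional-hazards outcomes) so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    pROC,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
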