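Package: tasselstate
Title: Tassel State Assessment from UAV Imagery of Maize Hybridization Fields
Version: 0.1.0
Authors@R: person("Field", "Phenomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess maize tassel states (detasseled, spikelet,
    emerged) from large UAV frames: center-anchored blocking patterns and
    sliding-window tiling, YOLO-format annotation handling with fixed-square
    box standardization and size sweeps, label-preserving data augmentation,
    a pluggable detector contract with a truth-conditioned mock detector,
    category-wise redundant-detection merging, detection and counting
    metrics (precision/recall/AP/mAP and ED/ACC/RMSE/MAE/MPAE/MDR), and a
    synthetic maize-canopy scene generator so the whole pipeline runs
    without field data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
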