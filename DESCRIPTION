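Package: flowcamtools
Title: Preprocessing, Biovolume Estimation and Classification for FlowCam Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for processing imaging flow cytometry (FlowCam) runs:
    unifies particle-property CSV exports across VisualSpreadsheet versions,
    flags duplicate vignettes and out-of-size-range particles, estimates
    per-particle biovolume and surface area from binary silhouettes by
    solid-of-revolution or distance-map methods, writes the annotation-ready
    LabelChecker CSV format, and optionally trains a shallow dual-input
    (image + particle properties) classifier. Includes a synthetic FlowCam
    run generator with ground truth for end-to-end testing without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
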