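Package: myodiff
Title: Automated Flow-Cytometry Quantification of Myoblast Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads and writes FCS 3.0 flow-cytometry files (including merged
    multi-dataset files), applies a control-calibrated gating strategy
    (debris exclusion, 99th-percentile GFP thresholding averaged over a
    double-negative and a MyHC+ control, GFP gene-dose expression bins, and
    kernel-density peak splitting of the myosin heavy chain channel), and
    reports the percentage of differentiated MyHC+ cells per GFP bin.
    Ships a seeded synthetic-experiment simulator with per-event ground
    truth so every analysis stage can be exercised without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
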