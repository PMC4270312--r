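Package: fretscreen
Title: High-Content FRET Calcium Imaging Screen Analysis
Version: 0.1.0
Authors@R:
    person("Plate", "Works", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phenotypic drug screens based on ratiometric
    FRET calcium imaging in 384-well plates: nuclei-seeded single-cell
    segmentation, YFP/CFP ratio extraction, delta-F/F0 peak-amplitude
    quantification with responder filtering, vehicle normalization and hit
    calling, plate QC against positive controls, one-way ANOVA with Dunnett
    many-to-one comparisons, four-parameter-logistic dose-response and ELISA
    calibration/back-calculation, secretase mechanism-of-action classification
    and substituent-class SAR summaries. A synthetic-data module generates
    ground-truthed image stacks, dose tables and ELISA plates so every stage is
    testable without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
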