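Package: robokin
Title: Robot-Derived Upper-Extremity Kinematics and Clinical Outcome Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes macro kinematic and kinetic metrics (aim, deviation, speed
    shape, dimensionless jerk, ellipse fits, joint independence, strength) and
    lognormal submovement micrometrics from robotic upper-extremity evaluation
    tasks, assembles session-level feature tables, performs correlation-based
    feature selection with collinearity pruning, and fits linear and shallow
    neural-network models of clinical outcome scales (FMA-UE, WMFT, BI, MRC)
    under patient-wise cross-validation with variance inflation factor
    diagnostics. Includes a synthetic-cohort generator with known ground truth
    for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    minpack.lm,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
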