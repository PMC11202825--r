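Package: duravol
Title: Lumbosacral Dural Sac Volumetry and Diagnostic Accuracy for Marfan
    Syndrome Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies dural ectasia from 3D label volumes of the
    lumbosacral spine: clipping planes through the intervertebral disc
    spaces partition the dural sac into level segments L3-S1, from which
    volumes, anteroposterior diameters, dural sac volume ratios (DSVR),
    diameter ratios (DSDR) and S1 scalloping are computed. Includes a
    synthetic 3D phantom generator with analytically known geometry, a
    cohort simulator matched to published per-group distributions in
    Marfan and non-Marfan patients, and a diagnostic-accuracy stage with
    empirical (DeLong) and closed-form binormal/lognormal ROC AUCs,
    Youden-optimal cut-offs and McNemar comparison of paired
    classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
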