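Package: sersquant
Title: Quantitative Dual-Metabolite Analysis of Ratiometric SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simultaneous quantification of glutathione (GSH) and
    hydrogen peroxide (H2O2) from surface-enhanced Raman spectra of a
    dual-reporter ratiometric gold nanoprobe. Provides spectrum I/O and
    preprocessing, a synthetic SERS simulator for probe calibration and
    tissue cohorts, the Relative Position Matrix (RPM) spectrum-to-image
    transform, a dual-branch batch-correlation convolutional regression
    network (DBCNet) with 1D/2D residual baselines trained from scratch in R,
    peak-ratio calibration and inverse quantification, spatial concentration
    maps, and a two-step logistic classifier for IDH1 genotype calling with
    ROC/AUC and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
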