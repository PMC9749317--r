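Package: vpcECG
Title: Digitization of 12-Lead ECG Printout Images and CNN Screening for
    Ventricular Premature Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts scanned standard 12-lead electrocardiogram (ECG)
    printout images (red-grid background, four vertical sub-images with
    three leads plus a long lead II rhythm strip) into clean 1250 x 12
    signal tensors by grid removal, binarization, pixel-column scanning,
    nearest-trace grouping, linear up-sampling, IIR low-pass filtering and
    per-lead normalization.  Provides three convolutional neural network
    classifier families (a 2-D image model over 256 x 512 x 3 inputs, a
    single-input 1-D model over the 1250 x 12 tensor, and a 12-branch
    multi-input 1-D model), trained with Adam and early stopping on
    patient-disjoint splits, and diagnostic evaluation (ROC/AUC, Youden
    optimal cut-point, sensitivity, specificity, predictive values, with
    stratified bootstrap confidence intervals).  A synthetic ECG renderer
    with per-pixel ground truth supports end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
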