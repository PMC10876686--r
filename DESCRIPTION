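Package: dcequant
Title: Quantitative and Semi-Quantitative DCE-MRI Pharmacokinetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacokinetic analysis of dynamic contrast-enhanced MRI:
    variable-flip-angle T10 mapping with B1 correction, spoiled
    gradient-echo signal-to-concentration conversion, arterial input
    function (AIF) construction (individual, six population-averaging
    variants, and Parker functional-form fitting), Tofts, extended Tofts
    and Brix model fitting (ROI-mean and voxel-wise), semi-quantitative
    metrics (AUC of the contrast-index curve, time-to-half-peak), and the
    agreement statistics used to compare AIF choices (ICC, concordance
    correlation). Includes a synthetic-study generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
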