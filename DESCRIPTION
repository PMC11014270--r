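Package: nirquant
Title: Deep-Learning Chemometrics for Quantifying Solid Adulterants in
    Coconut Milk from NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying solid adulterants (corn flour, tapioca
    starch) in coconut milk from near-infrared spectra. Provides a spectral
    data model with wavelength/wavenumber axis handling for benchtop FT-NIR
    (1102 features, 12,500-4000 cm-1) and portable Micro-NIR (125 features,
    908-1676 nm) instruments, a Gaussian-band mixture simulator that emulates
    the 15-level x 10-sample x 3-scan adulteration study design, standard
    normal variate (SNV) preprocessing, four one-dimensional deep regressor
    architectures (simple CNN, S-AlexNet-style, residual, and inception
    networks) trained with Adam and early stopping, an evaluation suite
    (R-squared, RMSE, Bias, ratio of percent deviation with quality bands),
    and finite-difference regression-coefficient interpretation with
    threshold-based important-wavelength selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
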