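Package: sersquant
Title: Machine-Learned Quantification of Sweat Metabolites from SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and machine-learned quantification of
    surface-enhanced Raman (SERS) spectra of sweat metabolites. Generates
    synthetic labeled mixture spectra with Lorentzian band models, chemically
    diverse backgrounds and measurement noise; preprocesses spectra
    (interpolation to a fixed wavenumber grid, min-max normalization,
    background subtraction, peak and signal-to-noise utilities); trains a
    semi-supervised autoencoder with per-metabolite logistic prediction heads
    for label-free concentration prediction of uric acid, lactate and
    tyrosine; explains predictions with gradient-based SHAP spectral feature
    importance; evaluates with repeated random-subsampling cross-validation,
    RMSE, R-squared and Bland-Altman agreement; and assembles chronological
    sweat profiles from sequentially filled microfluidic chambers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
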