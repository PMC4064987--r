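Package: dcegkm
Title: General Kinetic Model and Two-Stage Kinetic Analysis for DCE-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies contrast-agent leakage across the blood-brain barrier
    from dynamic contrast-enhanced MRI (DCE-MRI) time series using the
    two-compartment general kinetic model (Tofts model). Provides T1-based
    signal-to-concentration conversion, biexponential arterial input function
    fitting, closed-form tissue-curve fitting for the transfer constants
    Ktrans and Kep, and a two-stage estimator that splits the tissue curve at
    a known intervention time (e.g. a second focused-ultrasound irradiation),
    smooths it with a free-frequency Fourier series, resamples each segment
    and fits stage-wise transfer constants with a duration-weighted
    distribution-volume summary. A forward simulator of the 40-frame
    acquisition generates synthetic arterial and tissue curves so every
    estimator can be validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
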