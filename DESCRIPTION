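Package: eyespec
Title: Whole-Eye Spectral Sensitivity and Retinal Photoreceptor Topography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation of whole-eye spectral sensitivity from electroretinogram
    (ERG) flicker photometry, descriptors of ocular media transmittance and oil
    droplet filtering, mixed-effects comparison of short- to long-wavelength
    sensitivity ratios across temporal frequencies, optical-fractionator
    stereology, and thin-plate-spline retinal topography mapping. Includes a
    parameterised forward eye model and wholemount simulator that generate ERG
    trial sets and stereology sessions with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
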