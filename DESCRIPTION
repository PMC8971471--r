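Package: safyr
Title: Wheat Growth Monitoring and Yield Estimation by Assimilating
    Remotely Sensed Leaf Area Index into the SAFY Crop Model
Version: 0.1.0
Authors@R:
    person("Field", "Phenomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A daily light-use-efficiency crop growth simulator (SAFY)
    for winter wheat, coupled to a shuffled-complex-evolution global
    optimizer with PCA-based dimension recovery (SP-UCI) that calibrates
    the model's three sensitive parameters (emergence day, effective
    light-use efficiency, senescence temperature threshold) against leaf
    area index retrieved from canopy reflectance through vegetation-index
    inversion models. Biomass and grain yield follow from the calibrated
    simulation via a harvest index. Includes evaluation metrics (R2,
    RMSE, nRMSE with consistency classes), partial least squares
    regression for multi-index inversion, and a synthetic field-trial
    generator emulating a 48-plot factorial experiment so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
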