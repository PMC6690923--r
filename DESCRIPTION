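Package: queftsnpk
Title: Balanced NPK Uptake Requirements for Radish with the QUEFTS Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates balanced nitrogen, phosphorus and potassium uptake
    requirements for radish (Raphanus sativus L.) with the QUEFTS
    (Quantitative Evaluation of the Fertility of Tropical Soils) model.
    Provides a trial-table data model with per-plot derivation of nutrient
    uptake, harvest index and internal efficiencies; calibration of
    maximum-accumulation and maximum-dilution envelope constants from
    internal-efficiency percentiles; the linear-parabolic-plateau QUEFTS
    engine with forward yield prediction, balanced-uptake solving and
    requirement-curve generation on plant-uptake and fleshy-root-removal
    bases; model validation metrics (RMSE, nRMSE, mean error, paired
    comparison tests); and a synthetic on-farm trial database generator
    with known envelope parameters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
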