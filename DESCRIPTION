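Package: queftsr
Title: QUEFTS Soil Fertility Model for Maize in the Nigerian Savanna
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parameterizes and applies the QUEFTS (QUantitative Evaluation
    of the Fertility of Tropical Soils) model for maize in the Northern
    Nigerian savanna. Provides the forward supply-uptake-yield engine,
    zone-calibrated indigenous soil nutrient supply equations, fitting of
    all crop coefficients from nutrient omission trial data (multivariate
    outlier screening, harvest-index filtering, boundary-line
    physiological efficiencies, minimum uptakes, best-subset supply
    regressions, fertilizer recovery fractions), balanced N-P-K uptake
    requirement curves, yield validation statistics, and a synthetic
    trial generator for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
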