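Package: sorptherm
Title: Moisture Sorption Isotherms and Sorption Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits moisture sorption isotherm models (GAB, Peleg, Enderby) to
    equilibrium moisture content / water activity data at multiple temperatures,
    selects the best-fitting model, and derives sorption thermodynamics: net
    isosteric heat via Clausius-Clapeyron, differential entropy, Gibbs free
    energy, enthalpy-entropy compensation (isokinetic temperature), spreading
    pressure, sorption surface area, and optimal storage humidity. Ships a
    five-cultivar sweet cherry reference dataset, a synthetic-data generator
    with known ground truth, and an end-to-end reporting pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
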