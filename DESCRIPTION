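Package: drykin
Title: Thin-Layer Drying Kinetics, Moisture Diffusivity and Quality of
    Infrared-Convective Dried Produce
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing thin-layer drying experiments on sliced
    plant tissue dried under combined infrared and convective heating.
    Fits eleven semi-empirical thin-layer models (Newton, Page, modified
    Page, Henderson-Pabis and its modified form, logarithmic, Wang-Singh,
    Verma, Thompson, two-term, Midilli-Kucuk) to moisture-ratio curves by
    bounded Levenberg-Marquardt least squares and ranks them by the
    chi-square / RMSE / R-squared battery conventional in the drying
    literature.  Estimates effective moisture diffusivity from the
    one-term Fickian slab asymptote by the slope method, and Arrhenius
    activation energy from diffusivities at several temperatures.
    Computes physicochemical quality indices (CIELAB total colour
    difference, browning index, shrinkage ratio, rehydration ratio,
    water-activity classification) and fits rational-polynomial response
    surfaces linking responses to infrared power, airflow and slice
    thickness.  Includes a synthetic drying-experiment generator for
    validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
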