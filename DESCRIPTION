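Package: dropletdesign
Title: Performance Prediction and Design Automation of Microfluidic
    Droplet Generators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts droplet diameter and generation rate for
    flow-focusing single- and double-emulsion microfluidic generators from
    device geometry, fluid properties, and flow rates, and inverts those
    predictors to automate device and flow-rate design. Provides unit-safe
    closed-form relations (hydraulic diameter, capillary number,
    conservation-of-mass generation rate, generation-rate difference,
    Good-Girifalco interfacial tension), dataset curation and
    dimensionless featurization, scaling-law, neural-network and
    boosted-tree diameter surrogates with a consensus average,
    double-emulsion stability classification by generation-rate matching,
    cost-guided inverse design, and a synthetic benchmark generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
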