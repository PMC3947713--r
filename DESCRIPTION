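Package: proxyoutcome
Title: Proxy-Outcome Adjustment for Unmeasured Confounding and a
    Sufficient-Cause Simulation Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates exposure effects corrected for unmeasured confounding
    by subtracting the exposure association with a proxy (negative control)
    outcome -- an outcome not caused by the exposure but sharing correlated
    causes with the outcome of interest -- from the conventionally adjusted
    association, either on the log-odds scale (beta-hat = beta' - beta-tilde')
    or as a log odds-ratio offset in a logistic model. Includes a
    sufficient-component-cause Monte Carlo simulation framework that
    generates correlated binary covariates by a latent uniform-mixture
    threshold construction, builds outcomes from matched causal pairs with
    competing events and background causes, fits fact, conventional and
    proxy logistic models, classifies exposure effects under configurable
    decision rules, and aggregates replicate studies into cross-tabulated
    agreement, sensitivity and specificity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
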