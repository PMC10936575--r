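Package: firefar
Title: Counterfactual Attribution of Avoided Wildfire Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic counterfactual analysis of avoided wildfire
    impacts from paired ensembles of simulated final fire sizes. Estimates
    fire-size exceedance-probability curves by Gaussian kernel density
    estimation and empirical integration, computes fraction of attributable
    risk (FAR) and relative risk (RR) curves with threshold and percentile
    analysis and nonparametric bootstrap uncertainty bands, and includes a
    stochastic percolation fire-spread simulator for generating paired
    factual/counterfactual ensembles under fuel-treatment scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
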