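Package: belugapreg
Title: Pregnancy Classification and Pregnancy-Rate Estimation from Blubber Progesterone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning pregnancy status to cetaceans from blubber
    progesterone concentrations and for estimating population pregnancy rate
    from blindly sampled individuals. Implements three classification
    approaches (a fixed concentration threshold, a Bayesian Gaussian mixture
    on log concentrations with WAIC-guided choice of the number of clusters,
    and a Bayesian logistic regression that predicts unknown-status
    individuals as missing responses), immunoassay unit handling (per-tissue
    and per-lipid concentrations, lipid imputation and low-lipid exclusion),
    classification scoring against known reproductive states, and a
    colour-class maturity correction for the pregnancy-rate denominator.
    Includes a synthetic-data generator emulating the statistical structure of
    beluga carcass and biopsy sampling programs so the whole pipeline is
    testable without access to archived field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
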