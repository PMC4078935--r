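Package: mulard
Title: Genetic Selection of Mule-Duck Fatty-Liver Quality from Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-stage analysis behind selecting "foie gras" quality
    in mule ducks: chemometric calibration of liver melting rate and biochemical
    composition from near-infrared spectra (replicate averaging, SNV, gap-segment
    derivatives, PCA/Kennard-Stone calibration-set selection, PLS1 regression with
    five-group cross-validation and external validation), and Bayesian estimation of
    crossbred ("partial") genetic parameters under a two-parental-line sire-dam
    model fitted by Gibbs sampling, with partial heritabilities, genetic
    correlations, line-specific breeding values and selection-index accuracies.
    Includes a synthetic-data generator (pedigrees, breeding values, crossbred
    phenotypes, spectra) that reproduces the statistical structure the analysis
    assumes, so the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mixOmics
Config/testthat/edition: 3
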