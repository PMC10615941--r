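Package: diffscoresim
Title: Difference-Score Artefacts in Evidence-Accumulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting tools for studying correlations between
    condition difference scores of evidence-accumulation model parameters.
    Implements the Wiener diffusion first-passage-time density with
    maximum-likelihood fitting, the EZ-diffusion closed-form estimator, the
    linear ballistic accumulator with its defective likelihood, per-participant
    parameter-population generators for two-condition designs, difference-score
    correlation matrices with outlier-robust variants, and an eight-model
    family competition based on AIC/BIC and Akaike weights. The package
    reproduces, from synthetic data alone, the large spurious negative
    correlation between boundary-separation and non-decision-time difference
    scores that arises when no true condition difference exists in those
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2,
    rlang,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
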