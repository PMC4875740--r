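Package: molarcascade
Title: Dental Inhibitory Cascade Analysis with Bayesian Phylogenetic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test macroevolutionary predictions of the dental
    inhibitory cascade (DIC) model of lower molar proportions. Provides the
    model's analytic geometry (molar areas from the activator-inhibitor
    ratio, the molar-proportion line, morphospace region classification,
    the third-molar agenesis threshold), preparation of specimen-level
    morphometric data into corrected occlusal areas and species summaries,
    a Bayesian phylogenetic generalized linear mixed model (PGLMM) engine
    with Gibbs/latent-variable MCMC, within-group centering, Pagel's lambda,
    highest density intervals and region-of-practical-equivalence (ROPE)
    decision summaries, posterior-draw mediation analysis, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
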