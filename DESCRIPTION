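Package: tridap
Title: Differential Protein Abundance by Marginal, Elastic-Net and
    Spike-and-Slab Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies differentially abundant proteins in small-sample
    label-based proteomics experiments (p >> n) by three complementary
    statistical routes: per-protein marginal regression with Bonferroni
    family-wise error control, elastic-net penalized logistic regression
    tuned by nested cross-validation, and Bayesian spike-and-slab logistic
    regression (stochastic search variable selection) sampled by a
    Polya-Gamma augmented Gibbs sampler with Bayesian false discovery rate
    control. A crossed-random-effects linear mixed model estimates and
    removes replicate-by-protein batch effects before testing, with
    principal-component quality control. A synthetic-data generator with
    known ground truth reproduces the assumed generative model so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmnet,
    ggplot2,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
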