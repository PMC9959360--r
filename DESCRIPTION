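Package: stuntmap
Title: Bayesian Geostatistical Mapping of Childhood Stunting from DHS-Style Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-based geostatistics pipeline for small-area estimation of
    childhood stunting prevalence from DHS-style cluster surveys. Provides a
    synthetic survey generator with two-stage stratified cluster sampling,
    GPS geo-masking and Matern-correlated cluster risk; survey-weighted
    descriptive prevalence tables (Horvitz-Thompson ratio estimation with
    Taylor-linearized standard errors); circular-buffer extraction of climate
    covariates from rasters; a finite-element SPDE representation of the
    Matern (nu = 1) Gaussian random field on a triangulated mesh; Bayesian
    spatial and non-spatial logistic regression via Polya-Gamma-augmented
    Gibbs sampling with odds-ratio summaries; DIC and WAIC model comparison;
    gridded posterior prevalence prediction aggregated to administrative
    units with coherent credible intervals; and cluster-level hold-out
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    geosphere,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
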