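Package: mufunlab
Title: Multifunctionality and Functional Redundancy Analysis for Dominant-Species
    Suppression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing biodiversity-ecosystem multifunctionality in
    split-plot species-suppression experiments on ground-foraging ant communities.
    Builds mixed-trait functional spaces (Gower distance, incidence-weighted
    principal coordinates, trait groupings and dominant-species selection),
    computes Hill-number diversity, Raup-Crick compositional uniqueness and
    functional richness/dispersion, fits penalized-spline models of the species
    richness to functional richness relationship, runs multiple-thresholds
    multifunctionality analyses (T_min, T_max, realized maximum diversity effect),
    decomposes treatment effects into direct and diversity-mediated paths with
    multilevel models, and estimates species-function associations with
    randomization null models. Includes a synthetic-data generator that emulates
    the full split-plot suppression design with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    grDevices,
    lme4,
    mgcv,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
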