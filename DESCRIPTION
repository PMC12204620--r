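Package: songcline
Title: Song Divergence, Species Classification and Genetic Differentiation
    Across an Avian Contact Zone
Version: 0.9.0
Authors@R:
    person("Songcline", "Maintainers", email = "maintainers@songcline.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for studying song divergence between two
    sister songbird species (Spotted and Eastern towhees) whose ranges meet in
    a longitudinal contact zone.  Synthesizes towhee-like song bouts with known
    ground truth, segments syllables from spectrograms, measures sixteen song
    features per bout, locates the zone of species co-occurrence along
    longitude, evaluates species classifiers (LDA, random forest, gradient
    boosting, multilayer perceptron) with label-permutation nulls and
    region-stratified splits, and quantifies mitochondrial differentiation via
    pairwise Phi-ST and two-level AMOVA, isolation by distance (Mantel tests)
    and Procrustes concordance of trait space with geography.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    ape,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
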