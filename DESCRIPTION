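Package: grassflam
Title: Grass Flammability Traits, Fire-Spread Prediction and Phylogenetic
    Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting the three components of plant flammability
    (ignitability, sustainability, combustibility) from leaf- and plant-scale
    burn experiments on grasses, computing the structural and chemical traits
    that explain them (biomass quantity, vertical biomass-density slope,
    moisture content, leaf surface-area-to-volume ratio, effective heat of
    combustion), predicting community-scale ignitability with a single-class
    Rothermel surface fire-spread model parameterised from those traits, and
    relating traits to flammability with phylogenetic comparative statistics:
    Pagel's lambda signal estimation, phylogenetic generalized least squares,
    and a bivariate phylogenetic mixed model separating within- from
    across-species allometric slopes. A synthetic-study generator reproduces
    the full experimental design (species on a phylogeny, fresh/dry clump
    pairs, sigmoidal mass-loss series, vertical biomass profiles) with known
    ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    MASS,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
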