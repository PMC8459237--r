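Package: ventsucc
Title: Functional-Trait Succession Analysis for Vent Colonization Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing functional-trait succession in benthic
    invertebrate colonization time series, developed around an 11-year
    deep-sea hydrothermal-vent colonization experiment. Computes mixed-type
    species dissimilarity (Gower coefficient with Podani's tie-corrected
    ordinal extension), clusters species into functional guilds with an
    automatic dendrogram cutoff, tracks species and guild Hill diversity and
    Rao's quadratic entropy through time, and tests quadratic-in-time trends
    of trait modalities, guilds and diversity indices by multinomial logistic
    regression with randomization-deviance inference and quadratic OLS with
    randomization R-squared inference. Includes a synthetic-data generator
    with planted guild structure and known temporal trends so every pipeline
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    ape,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
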