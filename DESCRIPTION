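Package: zetaform
Title: Forms of Multisite Similarity (Zeta Diversity) Decline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes zeta diversity decline (the average number of species
    shared by increasing numbers of sites) from site-by-species matrices,
    classifies communities as exponential versus power-law decliners via
    Akaike weights on linearized model fits, implements the spatially
    implicit finite negative binomial sampling null model and
    matrix-perturbation simulation experiments that explain when each form
    arises, and computes community biodiversity properties (probability of
    interspecific encounter, Morisita aggregation, checkerboard C-score,
    pairwise Spearman association) with null-model standardized effect
    sizes, plus a synthetic-community generator and an end-to-end pipeline
    for comparing properties between forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
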