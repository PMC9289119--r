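Package: ecodensity
Title: Bird Population Densities in Geographical and Ecological Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes country-scale bird population densities in geographical
    space (individuals per unit surveyed area) and in ecological space
    (individuals per unit area of suitable habitat) from point-count census
    data and species habitat-preference vectors, quantifies habitat and diet
    specialization with the species specialization index (SSI), reduces
    morphological and reproductive trait blocks by principal component
    analysis, and relates densities to traits with phylogenetic generalized
    least squares under a Brownian-motion covariance structure, including
    all-subsets model dredging, delta-AIC model selection and full model
    averaging. A synthetic-data generator produces mosaic landscapes,
    communities with known specialization-density links, Brownian traits and
    perturbed phylogenies so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
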