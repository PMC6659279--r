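Package: fadesat
Title: Fatty-Acid Desaturation Indices and Phylogenetic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Delta-9 desaturation index and the double bond
    index from fatty-acid composition profiles of mammalian adipose tissue
    and blubber, and relates them to environment, latitude and hair density
    with phylogenetic generalized least squares (PGLS). Includes a
    from-scratch GLS engine with maximum-likelihood estimation of Pagel's
    lambda, AICc-based model selection with Akaike weights and evidence
    ratios, aggregation of fits across random resolutions of phylogenetic
    polytomies, and a seeded synthetic-data generator (Yule trees,
    lambda-scaled Brownian residuals, composition profiles with prescribed
    indices) so that the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
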