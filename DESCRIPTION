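Package: tickRI
Title: Communicative and Reproductive Interference Statistics for
    Two-Species Tick Surveys
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing adult tick survey data from cattle herds
    where two Amblyomma species (A. variegatum and A. hebraeum) meet.
    Implements niche-overlap indices (Schoener's D) for attachment-site
    preferences, checkerboard C-score co-occurrence null-model tests at
    host, attachment-site and cluster levels, sexual-isolation indices
    (PSI, PTI, IPSI, IAPSI) with bootstrap inference on 2x2 mating tables,
    beta-binomial logistic regression of con-specific mating proportions
    with within-host correlation, herd-level detection probability under
    imperfect inspection sensitivity, and a seeded hierarchical synthetic
    survey generator for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
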