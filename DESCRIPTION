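Package: clustdamage
Title: Multinomial Modelling of Clustered DNA Damage from Energy-Imparted Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts yields of simple and complex clustered DNA lesions
    (single-strand breaks, double-strand breaks and base damage) produced by
    ionizing radiation in a nucleosome-scale DNA segment. Energy imparted to a
    5 x 5 nm cylindrical target is converted to a number of damage-capable
    events through a smeared energy threshold; events are distributed over four
    outcomes (direct sugar-phosphate ionization, OH-radical production, direct
    base ionization, inert deposition) by a multinomial model, and an operator
    algebra with base-pair clustering probabilities resolves each event
    composition into a probability distribution over lesion classes of
    increasing complexity. A base-pair-level Monte-Carlo simulator provides an
    independent brute-force check of the algebra and estimates the clustering
    probabilities. Folding the per-energy damage probabilities with
    energy-imparted frequency spectra gives lesion yields per Gy and action
    cross-sections versus linear energy transfer for arbitrary radiation
    qualities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
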