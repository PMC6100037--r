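Package: vitisaroma
Title: Aroma Profiling and Consumer-Liking Prediction for Table Grapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning volatile-compound concentration tables from
    table-grape (Vitis vinifera) berries into interpretable aroma profiles and
    predicted consumer-liking scores. Implements odor activity values (OAV),
    primary and secondary aromatic-series aggregation and per-cultivar aroma
    fingerprints, and a single-response orthogonal partial least squares
    (OPLS) regression core with unit-variance scaling, seven-fold
    cross-validation, permutation validation, Hotelling's T-squared outlier
    screening and VIP-based key-compound selection. A seeded synthetic-cohort
    generator emulates the tissue-specific abundance structure of pulp and
    skin volatiles so that every stage of the pipeline can be exercised and
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
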