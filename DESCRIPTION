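Package: phagemix
Title: Rational Design and In Vitro Evaluation of Bacteriophage Cocktails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for composing and evaluating therapeutic
    bacteriophage cocktails against mastitis-associated Escherichia coli and
    Staphylococcus aureus. Implements plaque-assay titer estimation with a
    weighted dilution-series formula, classification of phage-induced growth
    inhibition from plate-reader kinetics, serial-dilution spot-test host-range
    calling, cross-sensitivity analysis of phage-resistant variants with
    receptor-prediction confirmation from mutated genes, a receptor-diverse
    greedy set-cover cocktail designer with resilience reporting, biofilm
    control effectiveness and milk-model log-reduction statistics, and storage
    stability summaries. A seeded synthetic assay-data generator reproduces the
    statistical structure of every assay so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
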