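Package: phosimpact
Title: Differential Phosphorylation-Impact Analysis of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether missense variants abolish, create, or rescue
    kinase binding at in-vivo phosphorylation sites. Scores kinase
    recognition motifs with position-specific scoring matrices, compares
    wild-type and mutant predictions per site under a configurable
    abolition rule, layers multiple-sequence-alignment conservation calls
    (tolerance, median conservation, Grantham GV/GD and A-GVGD classes),
    and stratifies results by biologically characterized versus
    uncharacterized sites. Ships a replay backend for recorded kinase
    predictions and a synthetic-data generator with planted truth labels
    so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
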