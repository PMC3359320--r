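Package: equiframe
Title: Scoring Health Policies for Human Rights Coverage of Vulnerable Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the EquiFrame methodology for standardized content
    analysis of health policy documents: a configurable lexicon of 21 Core
    Concepts of human rights and 12 Vulnerable Groups, key-language mention
    detection over sentence-segmented policy text, a 1-4 quality scoring
    scale aggregated to a concept-by-group score matrix via the max rule,
    the three summary coverage/quality indices with the High/Moderate/Low
    overall ranking, dual-rater reliability (raw agreement and Cohen's
    kappa) with consensus building, country benchmark tables, and a
    synthetic policy-corpus generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
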