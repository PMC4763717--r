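Package: diseasetalk
Title: Measuring Public Discussion of Diseases in Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how much a set of diseases is discussed in a
    social-media corpus and for correcting the two biases that dominate such
    measurements: word-sense ambiguity of disease names, corrected by sampled
    human appraisal of term mentions, and platform demographics, corrected by
    correlating against prevalence within the platform-user stratum. Includes
    lexicon construction from a consumer-health-vocabulary style thesaurus,
    corpus filtering and token-boundary term counting, correction-factor and
    validated-count estimation with inter-rater agreement statistics,
    tie-aware Spearman correlation with permutation inference, prevalence
    projection, and a synthetic-corpus generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
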