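Package: sentread
Title: Sentence-Level Surprisal, Semantic Relevance, and Reading-Speed Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sentence-level predictors of naturalistic reading
    behaviour and evaluates them against sentence reading speed. Three
    sentence-surprisal estimators are provided (chain-rule joint
    log-probability, length-normalised negative log-likelihood, and
    next-sentence-prediction surprisal) together with a memory-aware
    sentence-relevance score: a recency-weighted sum of cosine
    similarities between a target sentence's embedding and its
    neighbours' embeddings over a four-sentence window. Metrics are
    computed over pluggable language-model backends; bundled
    deterministic toy backends (uniform, bigram, bag-of-words,
    Jaccard next-sentence) make the full stack testable offline.
    A synthetic multilingual reading-data generator with known effect
    structure and a generalized-additive-mixed-model evaluation stage
    (AIC difference between base and full models, per-term
    significance, partial-effect curves) complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    mgcv,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
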