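Package: sleepfrag
Title: Multi-Resolution Sleep Fragmentation Analysis from Hypnograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies sleep fragmentation from scored hypnograms at
    conventional 30-s epoch and high-resolution 5-s mini-epoch scale.
    Computes sleep architecture summaries, stage transition indices per
    hour of total sleep time, discrete-time Markov transition probability
    matrices over the five sleep stages, a run-length taxonomy of brief
    wake periods, and split-night (first versus second night-half)
    stratification. A cohort statistics layer fits linear mixed-effects
    group comparisons with family and participant random intercepts,
    standardized effect sizes, and Benjamini-Hochberg control over the
    transition-probability grid. Includes a synthetic cohort generator
    with ground-truth transition matrices for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
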