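Package: mmdisten
Title: Multivariate Multiscale Modified Distribution Entropy for Multichannel Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the irregularity of multichannel physiological time
    series (EEG and similar) with a multivariate multiscale modified
    distribution entropy: composite delay-embedding vectors are built across
    channels, their pairwise distances are passed through a fuzzy exponential
    similarity, and the Shannon entropy of the binned similarity distribution
    is reported per coarse-graining scale. Includes seeded synthetic-signal
    generators (Gaussian, pink, chaotic logistic, sinusoid), batch feature
    extraction over scales, a feed-forward neural classifier trained with
    RMSprop on binary cross-entropy, stratified k-fold cross-validation with
    precision/recall/F1/accuracy reporting, and a command-line interface for
    the simulate/entropy/classify pipeline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
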