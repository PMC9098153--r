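Package: mhdual
Title: Dual Subjective-Objective Mental-Health Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating occupational mental-health
    screening scales and fusing them with language-derived affect scores.
    Provides fuzzy (outlier-downweighting) exploratory factor analysis for
    scale-dimension construction, a psychometric validation suite
    (Cronbach's alpha, test-retest reliability, criterion validity, KMO and
    Bartlett sampling-adequacy tests, item discrimination by the critical
    ratio method, readability), a multinomial naive Bayes sentiment
    classifier strengthened by SAMME AdaBoost for the text channel, a
    pluggable Gaussian prosody-feature emotion scorer for the speech
    channel, and weighted late fusion of objective scale scores with the
    subjective channels, including calibration metrics against interview
    ground truth. A synthetic-data module generates Likert responses from a
    latent common-factor model with outlier contamination, retest and
    criterion companions with target reliability and validity, labelled
    unigram text corpora, and full assessment cohorts with planted binary
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
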