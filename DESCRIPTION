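Package: morphgaze
Title: Statistical Morphology Models as Predictors of Eye-Tracking Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains statistical models of morphology -- a word unigram model,
    morph unigram and bigram models over linguistically segmented input, a
    minimum-description-length (MDL) segmentation model with a tunable
    corpus-weight hyperparameter, and a flat category-HMM variant -- and
    compares their per-word self-information (surprisal, in bits) as
    predictors of early and late eye-tracking measures of visual word
    recognition (first fixation duration, gaze duration, and their
    difference). Includes computation of trial-level gaze measures from
    fixation reports with standard trimming and exclusion rules,
    mixed-effects model comparison by deviance decrease and AIC, and a
    synthetic-data module generating a Zipfian agglutinative lexicon,
    stimulus and pseudoword sets, and simulated fixation data with known
    effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
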