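Package: ragacues
Title: Tonality and Rhythm Cues in Cross-Cultural Ratings of Musical
    Emotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tonal and rhythmic descriptors of raga-like
    melodic audio (tonic-interval histograms in cents with octave
    folding, minor-to-major tonality ratios, pulse clarity from the
    entropy of the onset-envelope fluctuation spectrum, and note-onset
    event density), generates synthetic drone-plus-melody stimuli with
    known ground truth, simulates listener rating surveys, compares
    emotion-rating labels and intensities between listener groups with
    Welch, Wilcoxon and Kolmogorov-Smirnov tests under Hochberg
    correction, partitions rating variance between tonality, rhythm and
    familiarity with iteratively reweighted least-squares bisquare
    regression, and contrasts reliance on the two cues across groups
    with a resampled odds-ratio statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    graphics,
    jsonlite,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
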