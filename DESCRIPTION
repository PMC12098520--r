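Package: adgsleep
Title: Adversarial Domain-Generalized Sleep Staging from Multichannel
    Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Five-class sleep staging (W, N1, N2, N3, REM) from multichannel
    polysomnography, built around a residual channel-attention feature
    extractor with a bidirectional GRU, trained adversarially against a
    subject (domain) discriminator through a gradient reversal layer so
    that learned features generalize to unseen subjects.  Includes a
    synthetic multi-subject PSG generator with per-subject domain shifts,
    an STFT spectrogram preprocessing pipeline, leave-one-subject-out
    cross-validation, fine-tuning with layer freezing, and full evaluation
    (per-class precision/recall/F1, macro-F1, Cohen's kappa, bootstrap
    confidence intervals).  All network forward and backward passes are
    implemented in base R linear algebra and verified against
    finite-difference oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
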