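Package: lcasonify
Title: Labeled Correlation Alignment of EEG Responses to Affective Music,
    with Envelope Sonification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples multichannel EEG responses to affective auditory stimuli
    through a two-step Labeled Correlation Alignment (LCA): per-modality
    supervised Centered Kernel Alignment (CKA) against a categorical emotion
    label kernel, followed by canonical correlation analysis of the projected
    feature blocks.  Provides phase-locking-value and Gaussian-kernel
    functional-connectivity feature extraction from windowed, band-limited
    EEG; windowed acoustic descriptor and envelope extraction from audio
    stimuli; electrode relevance back-projection; a silhouette-style partition
    quality statistic; leave-one-subject-out evaluation; and a compact
    vector-quantized variational autoencoder that sonifies EEG-selected
    features into acoustic envelopes.  A seeded synthetic-data module with
    planted phase coupling, label structure and a known canonical correlation
    makes every stage testable without any recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
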