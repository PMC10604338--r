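Package: mcheart
Title: Multi-Channel Heart-Sound Processing and Murmur Detection from
    Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting heart murmurs in phonocardiogram (PCG)
    recordings. Implements a multi-channel feature extractor that separates
    fundamental heart sounds (S1/S2) from systolic and diastolic murmur
    activity by Hilbert-envelope thresholding, producing stacked log-mel
    spectrogram channels plus a mean peak-interval feature; a light
    convolutional network with max-feature-map activation, residual
    connections, Swish activation and multi-head self-attention over time
    frames; spectrogram-level mixup and cutout augmentation; a cost-sensitive
    single-instance training loop with patient-level aggregation and
    unknown-class threshold fitting; and challenge-style weighted-accuracy
    scoring. A synthetic PCG cohort generator with ground-truth cardiac-cycle
    segments makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
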