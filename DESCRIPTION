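Package: eegvit
Title: Vision-Transformer Classification of EEG Wave Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying multichannel EEG recordings from wave
    images. Recordings are cut into overlapping fixed-duration slices,
    rendered as square grayscale images (time domain by bilinear resizing,
    frequency domain by per-channel discrete Fourier transform), and
    classified with a from-scratch Vision Transformer trained by
    backpropagation. Includes a synthetic-cohort simulator with
    band-structured EEG and delirium-like spectral slowing, a preprocessing
    chain (band-pass filtering, common-average re-referencing, epoching,
    ICA artifact removal), subject-grouped train/test splitting, and an
    experiment driver that sweeps slice length, window overlap and
    time-versus-frequency image encodings, demonstrating the
    minimum-detectable-frequency mechanism (f = 1/T) behind slice-length
    effects on accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
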