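Package: cortwave
Title: Quantification of Cortical Actin Wave Dynamics in Time-Lapse Fluorescence Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect, track, and characterize traveling cortical
    actin waves in single-channel fluorescence time-lapse movies, as seen on
    the basal membrane of giant Dictyostelium cells on flat and nanoridged
    substrates. Implements Lucas-Kanade optical flow with an
    eigenvalue-based reliability gate, intensity k-means wave segmentation
    with flow-coherence substructure division, overlap-based multi-object
    tracking, antipodal bimodal von Mises mixture fitting of flow
    orientations (directionality kymographs and electric-field reversal
    response times), and wave-population morphometrics including the
    exponential minimum-area versus duration boundary fit that yields the
    characteristic wave timescale. A seeded synthetic movie generator with
    full ground truth supports validation without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
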