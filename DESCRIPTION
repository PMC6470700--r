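Package: bedvitals
Title: Contactless Heart and Respiration Rate Monitoring from a
    Bed-Mounted Load-Cell Ballistocardiogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects individual heartbeats and respiration cycles in the
    longitudinal ballistocardiogram (BCG) measured by a load cell mounted
    under a bed. The raw force signal is separated into cardiac and
    respiratory components with linear-phase FIR and Butterworth band
    filters, candidate heartbeat waves are described by fixed-length
    feature vectors anchored at local maxima, and beats are recognised by
    unsupervised complete-link agglomerative clustering under a gated
    inverse-cosine dissimilarity. Includes reference QRS detection for a
    simultaneously recorded ECG, beat-to-beat evaluation of the BCG
    detections against the ECG, and a synthetic-signal generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
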