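Package: fecgsqa
Title: Signal Quality Assessment and Channel Selection for Non-Invasive
    Fetal Electrocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic signal-quality assessment of raw multi-channel
    trans-abdominal biopotential recordings for non-invasive fetal
    electrocardiography. Computes sixteen time- and frequency-domain
    signal quality indexes on 5-s segments, ranks them by minimum
    redundancy maximum relevance, trains a bagged decision-tree
    classifier to recognise abdominal channels carrying usable fetal
    ECG content, and evaluates the impact of the resulting channel
    selection on fetal QRS detection after multi-reference QRD-RLS
    maternal-ECG cancellation. Includes a synthetic abdominal-recording
    generator with ground-truth fetal/maternal R-peak trains and
    per-channel fetal signal-to-noise ratios, plus readers and writers
    for WFDB-style and delimited recordings and peak annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
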