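Package: apneascreen
Title: Sleep Apnea Screening from Wearable Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for screening
    sleep apnea from single-channel photoplethysmography (PPG) and pulse
    oximetry, as acquired by wearable ring or wrist devices. Includes
    baseline-drift removal and median denoising, IIR lowpass filtering with
    delay compensation, multiscale sample entropy with an overlap
    (sliding-window) coarse-graining scheme, pulse-peak detection by dyadic
    wavelet modulus-maxima pairing, pulse-rate-variability features,
    random-forest window classification, SpO2 desaturation gating against
    non-pathological artifacts, and apnea-hypopnea index (AHI) reporting.
    A synthetic-recording generator with known ground truth (beat times,
    apnea episodes, probe artifacts) makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    randomForest,
    e1071,
    class,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
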