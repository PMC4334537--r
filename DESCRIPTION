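Package: fhrv
Title: Fetal Heart Rate Extraction and Variability Analysis from Abdominal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the fetal heart rate from multichannel maternal
    abdominal electrocardiograms by adaptive maternal P-QRS-T cancellation
    (a Gaussian-weighted averaged QRS template paired with its
    Hilbert-transform quadrature as an orthogonal two-basis fit per beat,
    followed by mean P-T segment subtraction), detects fetal beats in the
    cleaned trace from the integrated Gabor time-frequency power in the
    10-20 Hz fetal QRS band with a sliding Tukey-window order-statistic
    envelope threshold, and computes a fetal heart-rate-variability battery
    (SDNN, quartile-mean heart-rate extrema, Poincare SD1/SD2, symbolic
    dynamics 0V/1V/2V). Ships a seed-deterministic synthetic abdominal-ECG
    generator with ground-truth beat times so the whole chain is testable
    offline, plus CSV and WFDB record input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
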