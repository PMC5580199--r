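Package: asthmawatch
Title: Wearable Multi-Sensor Asthma Attack Risk Assessment Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reimplementation of a smartwatch-based asthma risk
    platform: ingestion of time-stamped multi-sensor records (optical dust
    sensor, particulate matter, spirometry, accelerometer, heart rate),
    piecewise temperature/humidity dust-sensor calibration, stream cleaning
    and smoothing, physiological and environmental feature engineering
    (composite-acceleration energy expenditure, heart rate reserve, percent
    of personal-best spirometry), Asthma Control Test based risk labelling,
    and a three-class random-forest risk classifier with nested grid search
    under 10-fold cross-validation. Includes a synthetic sensor-stream
    generator emulating smoke and exercise exacerbation episodes, and a
    hybrid AES/RSA record envelope, so the full pipeline is testable
    without hardware or network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    openssl,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
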