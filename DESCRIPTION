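Package: ripecast
Title: Greenhouse Microclimate Forecasting, Tomato Ripening Kinetics, and
    Non-Destructive Quality Prediction from Fruit Color
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for predicting tomato fruit quality on the
    plant from RGB images and greenhouse sensor data. Provides quality control,
    gap filling and windowing of sensor time series; gray-world white balance,
    CIELAB a* extraction, surface color-ratio measurement and five-level
    maturity grading for masked fruit images; a stacked LSTM next-step
    forecaster for temperature, humidity and radiation; a GRU encoder with
    query-key-value attention that predicts red/yellow/green surface fractions
    from joint environment and color history; a multi-task feed-forward
    regressor mapping the normalized a* feature to six quality traits (FI,
    SSC, SS, TA, VC, LYC) with adaptively weighted losses; R2/MAE/RMSE
    reporting; and a seeded synthetic greenhouse simulator so the whole
    pipeline is trainable and testable without field data. All recurrent and
    feed-forward models are implemented in the package with batched
    backpropagation and Adam.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
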