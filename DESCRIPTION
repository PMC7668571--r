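Package: ventrc
Title: Lumped Resistance-Compliance Modelling of Pressure-Controlled
    Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates pressure-controlled mechanical ventilation with a
    lumped resistance-compliance network of the ventilator tubing system
    and patient lung, solved exactly at the cyclic (breath-to-breath)
    steady state.  Sizes the inspiratory flow restrictor needed to deliver
    a target tidal volume when two dissimilar patients share one
    ventilator, characterises circuit components from pressure-drop
    versus flow measurements with Tukey bi-square robust regression,
    estimates respiratory resistance and compliance from 50 Hz
    flow/pressure waveform logs, and generates synthetic waveform
    recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
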