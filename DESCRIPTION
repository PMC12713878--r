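Package: endotyper
Title: Obstructive Sleep Apnea Endotyping from Polysomnographic Airflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the four pathophysiological endotypes of obstructive
    sleep apnea (pharyngeal collapsibility, upper-airway muscle compensation,
    arousal threshold, and loop gain) from a routine polysomnographic airflow
    signal together with scored respiratory events, arousals, and sleep
    stages. Breaths are segmented from the flow trace, ventilation is
    normalized to a local eupneic baseline, a delayed first-order chemoreflex
    model is fitted to the unobstructed ventilation by constrained least
    squares to recover a continuous ventilatory-drive estimate, and the
    ventilation-versus-drive relationship is summarized as an endogram from
    which the traits are read. A closed-loop ventilatory-control simulator
    with known ground-truth traits makes the full pipeline testable without
    any real recording.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
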