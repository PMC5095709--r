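Package: difcanal
Title: Differential Two-Dye Canalogram Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies conventional aqueous outflow changes from paired
    fluorescein / Texas red canalogram time lapses of enucleated eyes.
    Provides a synthetic eye-phantom generator with known per-quadrant
    ground-truth flow, TIFF stack input/output with metadata sidecars,
    laterality-aware perilimbal quadrant ROIs, dye kinetics and
    self-quenching screening, estimation of the TR-to-FU normalization
    coefficient from control eyes, per-quadrant percent outflow change and
    flow rates in microliters per minute, and matched-pair group statistics
    with power-based sample-size calculation.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
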