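Package: rfidtrack
Title: Grid-Based Passive RFID Localization and Activity Estimation for
    Group-Housed Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning passive radio-frequency identification (RFID)
    registration logs from a floor-mounted antenna grid into per-animal
    locations and locomotor activity estimates. Provides a geometric model of
    the antenna grid (centre distances, switch units, Moore-neighbour
    adjacency), log parsing with forward-fill completion and a five-second
    false-switch filter, distance and duration-corrected activity summaries,
    exact and near (eight-neighbour) location validation against ground-truth
    annotation streams, agreement statistics (Fleiss' and Cohen's kappa,
    bootstrap Spearman rank correlation, repeated-measures correlation), and a
    synthetic movement-and-sensor simulator emulating tagged broilers in a pen
    with an RFID floor grid, a video observer and an ultra-wideband observer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
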