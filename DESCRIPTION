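Package: lasertherm
Title: Fluorescence Thermometry and Planning for Infrared-Laser Single-Cell Heat Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and planning infrared-laser heat-shock
    induction of gene expression in single cells of transparent embryos.
    Implements ratiometric fluorescence thermometry with a temperature-dependent
    red reporter (calibration fitting, laser ON/OFF temperature maps, per-cell
    temperature elevations), a phenomenological laser-heating model (linear
    power dependence at the focus, exponential spatial decay with a shared
    half-maximal distance, first-order step-response kinetics, pulsed
    duty-cycle operation), a planner that chooses laser power and ambient
    temperature to confine induction or ablation to a target cell, and
    morphometric analyses of neurite outgrowth, developmental staging and
    paired cell-division timing. A synthetic-data module generates image
    stacks, per-cell measurement tables, neurite tracks and division
    records with known ground truth, so every stage of the pipeline can be
    exercised and validated without microscope data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
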