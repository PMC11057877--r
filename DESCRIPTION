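Package: chromafish
Title: Receptor-Noise-Limited Colour Vision Modelling and Psychophysics for
    Tetrachromatic Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ultraviolet colour vision in reef fishes.
    Estimates visual-pigment peak sensitivities (lambda-max) from
    microspectrophotometry absorbance scans by Govardovskii A1/A2 template
    fitting, extracts ocular lens T50, computes receptor quantum catches with
    von Kries adaptation, chromatic distances (delta-S) under the log
    receptor-noise-limited model, noise-corrected Cartesian coordinates and
    hue angles in tetrahedral colour space, designs multi-primary LED stimuli
    (colour lines radiating from the achromatic point, grey distractor sets,
    intensity-bracketed distractor subsets), fits psychometric functions to
    binomial choice data to obtain discrimination thresholds at 0.5
    probability correct, and compares trichromatic against tetrachromatic
    visual models over a receptor-noise grid. A synthetic-data module
    generates display spectra, pigment scans and behavioural trials with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
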