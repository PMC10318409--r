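Package: flimox
Title: Oxygen-Controlled Microfluidic Cultivation Analysis via
    Frequency-Domain FLIM and Single-Cell Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for oxygen-controlled microfluidic single-cell
    cultivation experiments. Estimates fluorescence lifetimes from
    frequency-domain modulated image stacks with reference-slide
    calibration, converts lifetimes of an oxygen-sensitive ruthenium dye
    (RTDP) to dissolved-oxygen concentrations through a two-point
    Stern-Volmer calibration, characterizes the step response of the chip
    (plateau levels and 85/90/95 percent switching times), and quantifies
    label-masked time-lapse fluorescence at single-cell and population
    level (border filtering, per-cell intensities, overlap-based tracking,
    generation assignment, growth rates, intensity slopes and
    fold-changes). A synthetic-data module generates all pipeline inputs
    with known ground truth: first-order oxygen step responses, noisy
    modulated FLIM stacks via the forward Stern-Volmer model, and
    agent-based monolayer micro-colonies of rod-shaped cells with
    oxygen-gated GFP maturation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
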