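Package: pentaspec
Title: Spectroscopic Analysis of G-Quadruplex/Duplex Equilibria in
    Pentanucleotide Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the folding equilibria of guanine-rich
    short tandem repeats (such as the CANVAS-associated AGGGA pentanucleotide)
    from UV-absorption and circular dichroism (CD) spectroscopy. Computes
    thermal difference spectra (TDS), estimates melting temperatures from
    derivative extrema of baseline-corrected melting curves, quantifies
    cooling/heating hysteresis, decomposes measured CD spectra into
    G-quadruplex and non-G4 fractions by two-basis least squares, predicts
    composite CD spectra of multi-quadruplex structures, and performs the
    repeat-design arithmetic (G-run counting, potential G4-unit and tetrad
    concentrations, predicted species sizes). A synthetic-data module
    simulates equilibrium and kinetic (hysteretic) melting for species of
    molecularity 1, 2 and 4 and generates Gaussian-band CD/TDS spectra and
    noisy two-basis mixtures for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
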