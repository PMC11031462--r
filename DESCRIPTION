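Package: piolcalc
Title: Vergence-Based Refraction and Magnification Calculations for
    Phakic Intraocular Lenses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Paraxial thick- and thin-lens vergence optics for phakic
    supplementary intraocular lenses (PIOLs). Computes the
    spectacle-plane refraction correction and the relative change in
    lateral magnification for four cornea/PIOL model scenarios,
    reconstructs implantable-collamer-lens-like meniscus designs from
    labelled equivalent powers via the Gullstrand thick-lens equation,
    generates synthetic anterior-segment biometry cohorts, and fits
    stepwise-selected linear and quadratic prediction models for the
    refraction correction and the magnification change over the full
    lens power schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
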