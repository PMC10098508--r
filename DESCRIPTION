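Package: qdsted
Title: Simulation and Analysis of STED Nanoscopy of Blinking Quantum Dots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of stimulated emission depletion
    (STED) nanoscopy images of blinking quantum dots, together with a
    point-scanning acquisition simulator that generates matched synthetic
    data. Includes analytic point-spread-function models and the
    depletion-power resolution law, STED minus STED-only background
    subtraction, blinking-mask and blinking-pixel-ratio statistics,
    integrated-brightness measurement, Lorentzian and Gaussian line-profile
    fitting for resolution estimation, single-versus-cluster classification
    from donut-shaped direct-excitation emission, endocytosis colocalization
    metrics (fraction of particles inside vesicle masks, single fraction
    parameter, distance to the nearest microtubule), and spectral
    bleed-through quantification for multicolour imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
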