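Package: nitrilefields
Title: Electric Fields at Nitrile Vibrational Probes from Force-Field Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate protein electric fields sensed by nitrile
    (C=N) vibrational Stark probes. Computes electric fields and
    electrostatic-potential maps from per-atom parameter sets at three
    levels of detail (point charges, permanent multipoles, mutually
    induced dipoles with Thole damping) and projects them onto the
    nitrile bond axis in MV/cm. Classifies frames as hydrogen bonding or
    non-hydrogen bonding by geometric criteria, deconvolves field
    distributions into the two populations, extracts dwell times and fits
    a two-state first-order exchange model, fits Gaussian surfaces to 2D
    hydrogen-bond geometry histograms, fits IR absorption bands, and
    compares simulation-derived fields with transition-dipole-derived
    experimental fields via errors-in-both-variables (York) weighted
    regression with confidence bands. Includes generators for synthetic
    switching trajectories, toy probe/donor scenes, geometry samples and
    spectra with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
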