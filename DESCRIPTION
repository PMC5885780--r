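Package: photokin
Title: Kinetic Modelling and Global Analysis of Flavoprotein Photoactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the light-driven reduction of oxidized flavin
    cofactors in photolyases and cryptochromes by transient absorption
    spectroscopy. Provides a registry of species absorption spectra with
    molar-absorptivity anchor points and radical-pair difference spectra, a
    first-order kinetic-network engine for photocycle schemes (branching
    ratios, observed vs. intrinsic time constants, cascade quantum yields,
    kinetic isotope effects), a synthetic flash-photolysis data generator with
    Gaussian instrument-response convolution and seeded noise, global mono- and
    biexponential Levenberg-Marquardt fitting with shared time constants,
    least-squares decomposition of amplitude spectra onto candidate
    radical-pair difference spectra, and relative actinometric quantum-yield
    determination against a ruthenium tris-bipyridine reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
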