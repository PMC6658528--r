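Package: photocycler
Title: Photocycle Kinetics and Spectroscopy of Desensitizing Channelrhodopsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing light-gated anion channels with a single-photocycle
    desensitization mechanism. Simulates four-state (dark, K, L, M) photocycle kinetics
    under arbitrary piecewise-constant light protocols and converts open-state occupancy
    to photocurrent; performs global lifetime analysis of time-resolved absorption data
    (sequential compartment models, variable projection, EADS/DADS transforms, SVD-based
    kinetic decomposition of FTIR difference spectra); implements patch-clamp photocurrent
    analysis (peak/stationary extraction, desensitization metrics, exponential kinetics,
    reversal potentials, Nernst and bi-ionic permeability ratios, Weibull action-spectrum
    fits, double-pulse recovery) and Henderson liquid-junction potentials; and processes
    steady-state spectra and pH titrations (Savitzky-Golay smoothing, difference spectra,
    sub-maxima detection, Boltzmann pK fits). Seeded synthetic-data generators with
    ground-truth registries support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
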