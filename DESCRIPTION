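Package: osmigrate
Title: Osmotic Engine Model of Confined Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state multi-phase model of actin-water-ion coupled cell
    migration in confining channels (the osmotic engine mechanism). Couples
    two-phase cytosol/actin-network mechanics to electroneutral Nernst-Planck
    ion transport with pump-leak membrane fluxes (passive tension-gated
    channels, Na+/K+ ATPase, Na+/H+ exchange, Cl-/HCO3- exchange) and solves
    the resulting one-dimensional boundary-value problem with a damped Newton
    continuation solver. Includes scenario sweeps over channel-polarization
    ratios, least-squares parameter fitting to single-cell velocity
    observations, synthetic-data generators with known ground truth, and the
    quantification procedures used alongside such experiments (front-to-rear
    fluorescence polarity ratios, trajectory velocity and mean squared
    displacement, spheroid shape metrics).
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
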