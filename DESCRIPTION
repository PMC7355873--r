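Package: vibhole
Title: Isotope Effects on NMR Shieldings via Difference-Dedicated VPT2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Second-order vibrational perturbation theory (VPT2) for zero-point
    isotope effects on NMR chemical shieldings and on molecular geometry, and the
    difference-dedicated (DD-VPT2) reformulation that concentrates the isotopologue
    difference into a small set of weighted vibration modes. Includes the a-priori
    local comparators loc-VPT2 and the local-mode zero-point-level (LMZL) model with
    an optional centrifugal correction, vibration-hole descriptors (r_z/r_g
    parameters, mean-square amplitudes, amplitude covariances and their isotope
    effects), synthetic anharmonic model systems with analytic potential and
    shielding surfaces, sinc-DVR grid oracles for 1D/2D subsystems, a YAML job
    schema, and Molden/XYZ exporters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
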