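Package: helixvalid
Title: Validation of Helical Symmetry Parameters Against Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to check whether a set of helical symmetry parameters
    (twist, rise, axial symmetry) is consistent with a 3D cryo-EM density
    map. Reads and writes MRC/CCP4 volumes, determines helical parameters
    directly from a map via cylindrical unwrapping and 2D lattice
    autocorrelation, compares deposited and map-derived parameters with
    normalized-difference, radius-aware vector and symmetrize-and-correlate
    metrics, detects the characteristic error classes found in archived
    helical depositions (missing, incorrect, swapped, sign-flipped and
    partial-symmetry parameters), and quantifies the resolution benefit of
    full versus partial helical symmetry via Fourier shell correlation of
    symmetrized half-maps. Includes a synthetic helical map generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
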