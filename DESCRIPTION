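Package: sobpbio
Title: Mixed-Field Radiobiology and Profile Comparison for Spread-Out
    Bragg Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for computational radiobiology of ion-therapy beams.
    Builds spread-out Bragg peaks (SOBP) from analytic pristine
    Bragg-peak kernels via non-negative least-squares weight design,
    converts per-depth mixed radiation-field dose spectra into
    cell-survival, RBE and Gy-Eq depth profiles using dose-averaged
    linear-quadratic coefficients (Zaider-Rossi mixing), aggregates
    multi-run Monte Carlo output with standard-error propagation, and
    quantitatively compares paired depth profiles from two transport
    engines with RMSE and 1D gamma-index (DD/DTA) analysis with
    TG-218-style verdicts.  A synthetic generator emulates two
    near-identical transport codes with controllable range shift,
    fragmentation-tail scaling and per-run statistical noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
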