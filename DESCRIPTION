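Package: tersim
Title: Tip-Enhanced Raman Imaging from Locally Integrated Polarizability Densities
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates tip-enhanced Raman spectroscopy (TERS) images and
    spectra by locally integrating Raman polarizability densities under a
    confined plasmonic near field. Provides Gaussian-cube volumetric I/O on
    rectilinear grids, parametrized Lorentzian/Gaussian near-field profiles
    with per-axis FWHM semantics, finite-difference construction of complex
    (resonant) Raman polarizability densities from displaced-geometry
    densities, a tip-scan engine producing per-mode and band-combined TERS
    images, differential Raman cross sections with Boltzmann thermal factors,
    and an analytic synthetic-density generator so the entire pipeline can be
    exercised without quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
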