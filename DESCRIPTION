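Package: excitonic
Title: Exciton Models, Electric-Field Analysis and Simulated Spectroscopy for
    Chlorophyll Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pigment-protein antenna complexes such as the
    fucoxanthin-chlorophyll protein (FCP) of diatoms with Frenkel exciton models.
    Builds exciton Hamiltonians from pigment geometries or plain-text tables,
    ranks site-energy ladders, evaluates Coulomb electric fields at chlorophyll
    ring atoms and analyses Stark-shift scans (shifts, susceptibility ratios,
    difference-dipole fits), constructs and extracts bath spectral densities,
    computes second-order cumulant linear absorption with pigment-pool
    decomposition, and propagates excitons over fluctuating Hamiltonians (NISE)
    for population transfer and two-dimensional electronic spectra with
    ground-state bleach, stimulated emission and excited-state absorption
    pathways. Includes a synthetic-data module that generates FCP-like
    networks, charge environments and Gaussian energy-gap trajectories so the
    whole chain runs without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
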