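Package: dsdge
Title: Direct Water Saturation Dynamic Glucose Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dynamic glucose enhanced (DGE) MRI
    based on exchange broadening of the direct water saturation (DS) line in
    Z-spectra. Provides a multi-pool Bloch-McConnell simulator for pulsed
    saturation of water plus glucose hydroxyl proton pools, compartmental
    brain-tissue models (blood, extravascular extracellular space, cell) with
    signal-level mixing, single-Lorentzian linewidth fitting of DS spectra,
    the DS-DGE post-processing pipeline (per-dynamic linewidth maps, baseline
    outlier rejection, relative linewidth change and area-under-curve maps,
    region-of-interest time curves), and a seeded digital head phantom that
    generates complete dynamic Z-spectral image series for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
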