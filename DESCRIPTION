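Package: bilayr
Title: Lipid Bilayer Structure, Probe Transport and DSC Thermogram Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of lipid bilayer simulations and
    differential scanning calorimetry (DSC) thermograms, aimed at studies of
    membrane-modifying small molecules. Computes bilayer structural
    observables (area per lipid, thickness, mass-density profiles, leaflet
    interdigitation as a fraction of mass overlap, deuterium order parameters
    |SCD|, geometric hydrogen-bond counts), probe-particle transport
    quantities (partition coefficient, anisotropic mean-squared-displacement
    diffusion coefficients, solubility-diffusion membrane permeability
    Pm = Dm*Kp/delta), and thermotropic phase-transition parameters (Tm,
    transition width, enthalpy, scan hysteresis, dose-response delta tables).
    Includes a synthetic-data module that generates geometric bead-chain
    bilayers, overdamped Langevin probe trajectories on a region-dependent
    diffusivity field, and two-state van't Hoff thermograms with fully known
    ground truth, plus readers and writers for multi-frame GRO, multi-MODEL
    PDB, extended XYZ and two-column thermogram CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
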