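Package: lobehf
Title: Screened Gaussian-Lobe Hartree-Fock for Molecular and Biomolecular
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Minimal-basis all-electron restricted Hartree-Fock built
    entirely on displaced s-type Gaussian (lobe) basis functions, with
    two-tier screening of electron repulsion integrals (density-relevance
    thresholds and smoothly switched Coulomb distance cut-offs), a
    divide-and-conquer mode with chemically informed hydrogen capping and
    density-matrix merging, real-time time-dependent Hartree-Fock UV/Vis
    absorption spectra, Mulliken-style atomic energy profiles for
    structure assessment, and analytic nuclear gradients driving BFGS
    structure optimisation and microcanonical molecular dynamics.
    Includes readers and writers for XYZ, PDB, Gaussian cube and
    two-column spectrum files, and deterministic synthetic-structure
    generators (water clusters and shells, polyene chains, capped
    polyglycine) so the whole stack is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
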