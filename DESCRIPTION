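Package: pepfold2d
Title: Coupled 2D Backbone Torsion Potentials with Hydrogen-Bond
    Polarization for Peptide Folding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for CMAP-style coupled two-dimensional backbone torsion
    potentials and their use in desk-scale peptide folding studies. Fits a
    double Fourier series to tabulated (phi, psi) torsion energy grids and
    evaluates the smooth surface with analytic partial derivatives and
    per-atom Cartesian forces; applies a distance-dependent exponential
    charge-transfer (polarization) model along backbone hydrogen bonds;
    samples torsion surfaces with Metropolis and replica-exchange Monte
    Carlo over configurable temperature ladders; and analyses the resulting
    ensembles with the weighted histogram analysis method (WHAM), specific
    heat and melting temperature extraction, free-energy landscapes over
    reaction coordinates, Kabsch RMSD, radius of gyration, K-means
    conformational clustering, Ramachandran secondary-structure populations
    and Karplus 3J(HN,HA) couplings. Includes deterministic builders for
    ideal peptide fixtures (helices, hairpins, extended chains) and
    multi-model PDB input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
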