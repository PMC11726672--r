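Package: qcensemble
Title: Conformer Ensemble Thermochemistry, Thermodynamic-Cycle pKa, and
    Structure-Ensemble Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-quantum-chemistry analysis of ligand conformer ensembles
    and receptor structure ensembles. Deduplicates conformers by rotational
    constants and energies, computes rigid-rotor/harmonic-oscillator
    thermochemistry with frequency scaling, extrapolates electronic energies
    to the complete-basis-set limit, assembles Gibbs free energies and
    Boltzmann populations, evaluates aqueous pKa from a proton-based
    thermodynamic cycle, performs Kabsch superposition and region RMSD
    analysis with optimal like-element atom matching, and runs Cartesian
    principal component analysis and RMSD clustering on C-alpha structure
    ensembles. Includes synthetic-data generators with planted truths so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    ape,
    grDevices,
    graphics,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
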